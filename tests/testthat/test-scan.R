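test_that("single-case statistic behaves at its landmarks", {
  # rest values with exact mean 0.05 and sd 0.02, reference group of 45
  z <- as.numeric(scale(seq_len(45)))
  rest <- 0.05 + 0.02 * z
  beta <- rbind(case = c(x1 = 0.34), matrix(rest, ncol = 1))
  rownames(beta) <- c("case", sprintf("R%02d", 1:45))
  colnames(beta) <- "cg1"
  r <- single_case_test(beta, "case")
  expect_equal(r$rest_mean, 0.05)
  expect_equal(r$rest_sd, 0.02)
  expect_equal(r$n_rest, 45L)
  expect_equal(r$df, 44L)
  expect_equal(r$t_stat, 0.29 / (0.02 * sqrt(1 + 1 / 45)), tolerance = 1e-12)
  expect_equal(r$t_stat, 14.34, tolerance = 1e-3)
  # p checked against numerical integration of the t density
  p_num <- 2 * integrate(function(u) dt(u, df = 44), r$t_stat, Inf,
                         rel.tol = 1e-12)$value
  expect_equal(r$p, p_num, tolerance = 1e-9)
  expect_identical(r$direction, "hyper")

  # x at the rest mean: t = 0, p = 1
  beta["case", 1] <- 0.05
  r0 <- single_case_test(beta, "case")
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p, 1)

  # zero-variance reference: sd floored, p collapses to 0, direction hyper
  beta[-1, 1] <- 0.05
  beta["case", 1] <- 0.34
  rz <- single_case_test(beta, "case")
  expect_equal(rz$rest_sd, 1e-6)
  expect_lt(rz$p, 1e-100)
  expect_identical(rz$direction, "hyper")
})

test_that("single-case test equals the pooled two-sample t oracle", {
  set.seed(42)
  for (rep in 1:20) {
    ns <- sample(12:40, 1)
    beta <- make_beta(ns, 8, seed = rep)
    beta[sample(length(beta), ns)] <- NA
    s <- sample(rownames(beta), 1)
    r <- single_case_test(beta, s)
    for (j in seq_len(ncol(beta))) {
      x <- beta[s, j]
      rest <- beta[setdiff(rownames(beta), s), j]
      rest <- rest[!is.na(rest)]
      if (is.na(x) || length(rest) < 10) {
        expect_true(is.na(r$t_stat[j]))
      } else {
        o <- oracle_pooled_t(x, rest)
        expect_lt(abs(r$t_stat[j] - o$t), 1e-10)
        expect_lt(abs(r$p[j] - o$p), 1e-10)
        expect_identical(r$df[j], o$df)
      }
    }
  }
})

test_that("FDR adjustment matches a literal step-up oracle and propagates NA", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  q <- adjust_fdr(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.01, 0.02)))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0,1\\]")

  grid <- c(0.001, 0.01, 0.02, 0.04, 0.05, 0.2, 0.5, 0.8, 1)
  set.seed(7)
  for (len in 1:8) {
    for (rep in 1:40) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(adjust_fdr(p), oracle_bh(p), tolerance = 1e-12)
    }
  }
  # q is never below p
  set.seed(8)
  p <- runif(200)
  expect_true(all(adjust_fdr(p) >= p - 1e-12))
})

test_that("region calling enforces run length, direction and gaps", {
  mf <- make_manifest(6)
  pr <- mf$probe_id

  # two significant consecutive probes: below min_run, no region
  res <- make_results(pr, q = c(0.001, 0.001, 0.5, 0.5, 0.5, 0.5))
  expect_equal(nrow(call_regions(res, mf)), 0L)

  # five significant probes: one region spanning them
  res <- make_results(pr, q = c(rep(0.001, 5), 0.5))
  reg <- call_regions(res, mf)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_probes, 5L)
  expect_equal(reg$start, mf$pos[1] - 1)
  expect_equal(reg$end, mf$pos[5])
  expect_identical(reg$probe_ids, paste(pr[1:5], collapse = ","))

  # direction flip in the middle kills the run
  res <- make_results(pr[1:3], q = rep(0.001, 3),
                      direction = c("hyper", "hypo", "hyper"))
  expect_equal(nrow(call_regions(res, mf)), 0L)

  # an oversized gap splits a run
  mf_gap <- probe_manifest(data.frame(
    probe_id = pr, chrom = "chr1",
    pos = c(100L, 200L, 300L, 5000L, 5100L, 5200L)))
  res <- make_results(pr, q = rep(0.001, 6))
  expect_equal(nrow(call_regions(res, mf_gap)), 1L)          # unlimited gap
  reg2 <- call_regions(res, mf_gap, max_gap = 1000)
  expect_equal(nrow(reg2), 2L)
  expect_equal(reg2$n_probes, c(3L, 3L))

  # chromosome change always breaks
  mf_chr <- probe_manifest(data.frame(
    probe_id = pr, chrom = rep(c("chr1", "chr2"), each = 3),
    pos = rep(c(100L, 200L, 300L), 2)))
  reg3 <- call_regions(res, mf_chr)
  expect_equal(sort(reg3$chrom), c("chr1", "chr2"))

  # unknown probe is a named hard error
  expect_error(call_regions(make_results("cgXXXX", 0.001), mf), "cgXXXX")
})

test_that("classification matches the two observed constitutional cases", {
  reg <- data.frame(mean_beta_carrier = c(0.34, 0.18, 0.26, 0.2499, 0.05,
                                          0.34, 0.75, 0.4),
                    mean_beta_rest = c(0.05, 0.03, 0.05, 0.05, 0.05,
                                       0.20, 0.05, 0.05),
                    direction = c(rep("hyper", 7), "hypo"))
  expect_identical(classify_region(reg),
                   c("monoallelic", "mosaic", "monoallelic", "mosaic",
                     "low_level", "hypermethylated", "hypermethylated",
                     "hypomethylated"))
})

test_that("island annotation respects half-open overlap semantics", {
  isl <- island_set(c("chr1", "chr1"), c(1000, 3000), c(2000, 4000),
                    c("CGI_A", "CGI_B"))
  reg <- data.frame(
    chrom = "chr1",
    start = c(1200, 500, 1500, 2000),
    end = c(1400, 1000, 3500, 2500),
    islands = "", stringsAsFactors = FALSE)
  out <- annotate_islands(reg, isl)
  expect_identical(out$islands[1], "CGI_A")      # inside
  expect_identical(out$islands[2], "")           # touches start only
  expect_identical(out$islands[3], "CGI_A;CGI_B")# spans both
  expect_identical(out$islands[4], "")           # begins at island end
})

test_that("cohort scan recovers a spiked epimutation and nothing else", {
  cfg <- sim_config(n_samples = 46, n_probes = 3000, spikes = list(
    spike_spec(sample = 7, island = 2, f = 1, lambda = 0.7)), seed = 123)
  sim <- simulate_cohort(cfg)
  fit <- scan_cohort(sim$beta, sim$manifest, sim$islands)
  expect_s3_class(fit, "epi_scan")
  expect_equal(nrow(fit$regions), 1L)
  expect_identical(fit$regions$sample, "S07")
  expect_identical(fit$regions$probe_ids, sim$truth$probe_ids)
  expect_identical(fit$regions$classification, "monoallelic")
  expect_identical(fit$regions$islands, "CGI002")
  expect_equal(fit$per_sample$n_regions[7], 1L)
  expect_output(print(fit), "monoallelic=1")
})

test_that("scan is invariant to sample order and to manifest row order", {
  cfg <- sim_config(n_samples = 20, n_probes = 800, spikes = list(
    spike_spec(3, island = 1, f = 1, lambda = 0.7)), seed = 17)
  sim <- simulate_cohort(cfg)
  fit <- scan_cohort(sim$beta, sim$manifest, sim$islands)
  set.seed(1)
  perm <- sample(nrow(sim$beta))
  fit_perm <- scan_cohort(sim$beta[perm, ], sim$manifest, sim$islands)
  expect_equal(fit$regions, fit_perm$regions)
  # shuffled manifest rows are re-sorted on construction
  mf_shuf <- probe_manifest(as.data.frame(sim$manifest)[
    sample(nrow(sim$manifest)), ])
  fit_shuf <- scan_cohort(sim$beta, mf_shuf, sim$islands)
  expect_equal(fit$regions, fit_shuf$regions)
})

test_that("scan_cohort agrees with the composable per-step pipeline", {
  cfg <- sim_config(n_samples = 16, n_probes = 400, spikes = list(
    spike_spec(2, island = 1, f = 1, lambda = 0.7)), seed = 31)
  sim <- simulate_cohort(cfg)
  sim$beta[sample(length(sim$beta), 200)] <- NA
  fit <- scan_cohort(sim$beta, sim$manifest, sim$islands)
  res <- do.call(rbind, lapply(rownames(sim$beta), function(s) {
    r <- single_case_test(sim$beta, s)
    r$q <- adjust_fdr(r$p)
    r
  }))
  reg <- annotate_islands(call_regions(res, sim$manifest), sim$islands)
  rownames(reg) <- NULL
  expect_equal(fit$regions, reg)
  expect_equal(fit$n_untestable, sum(is.na(res$p)))
})

test_that("region calls shrink monotonically in min_run and q threshold", {
  cfg <- sim_config(n_samples = 20, n_probes = 1500, spikes = list(
    spike_spec(2, island = 1, f = 1, lambda = 0.7),
    spike_spec(9, island = 4, f = 0.5, lambda = 0.9)), seed = 11)
  sim <- simulate_cohort(cfg)
  counts_run <- vapply(2:7, function(mr) {
    nrow(scan_cohort(sim$beta, sim$manifest, min_run = mr)$regions)
  }, numeric(1))
  expect_true(all(diff(counts_run) <= 0))
  counts_q <- vapply(c(0.05, 0.005, 5e-4, 5e-6, 5e-9), function(qt) {
    nrow(scan_cohort(sim$beta, sim$manifest, q_threshold = qt)$regions)
  }, numeric(1))
  expect_true(all(diff(counts_q) <= 0))
})

test_that("a null cohort yields essentially no false regions", {
  fit <- scan_cohort(simulate_cohort(sim_config(n_probes = 3000,
                                                seed = 77))$beta,
                     simulate_cohort(sim_config(n_probes = 3000,
                                                seed = 77))$manifest)
  expect_lte(nrow(fit$regions), 1L)
})

test_that("probes with too few reference values are untestable", {
  beta <- make_beta(14, 5, seed = 4)
  beta[2:14, 3] <- NA  # probe 3: zero rest values for S01
  beta[1:6, 4] <- NA   # probe 4: rest n = 8 < 10 for any sample
  r <- single_case_test(beta, "S01")
  expect_true(is.na(r$t_stat[3]))
  expect_true(is.na(r$p[4]))
  expect_false(anyNA(r$p[c(1, 2, 5)]))
  fit <- scan_cohort(beta, make_manifest(5))
  expect_gt(fit$n_untestable, 0)
})
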
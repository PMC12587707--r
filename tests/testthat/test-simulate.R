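test_that("spike expectation follows the allelic-fraction mixture", {
  cfg1 <- sim_config(n_probes = 500, spikes = list(
    spike_spec(1, island = 1, f = 1, lambda = 0.7)), seed = 1)
  sim1 <- simulate_cohort(cfg1)
  # f=1, lambda=0.7, m=0.05: e = 0.7*(0.5 + 0.025) = 0.3675, a monoallelic
  # read in the 0.26-0.42 band
  expect_equal(sim1$truth$expected_beta, 0.3675)
  expect_identical(sim1$truth$label, "monoallelic")

  cfg2 <- sim_config(n_probes = 500, spikes = list(
    spike_spec(3, island = 2, f = 0.35, lambda = 1)), seed = 1)
  sim2 <- simulate_cohort(cfg2)
  # f=0.35, lambda=1: e = 0.65*0.05 + 0.35*0.525 = 0.21625, mosaic-like
  expect_equal(sim2$truth$expected_beta, 0.21625)
  expect_identical(sim2$truth$label, "mosaic")
})

test_that("vanishing allelic fraction collapses to background", {
  cfg <- sim_config(n_probes = 500, spikes = list(
    spike_spec(1, island = 1, f = 1e-9, lambda = 0.7)), seed = 5)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$expected_beta, 0.05, tolerance = 1e-6)
  probes <- strsplit(sim$truth$probe_ids, ",")[[1]]
  spiked <- sim$beta["S01", probes]
  expect_lt(abs(mean(spiked) - 0.05), 0.05)
})

test_that("generated beta values stay in [0,1] and are reproducible", {
  cfg <- sim_config(n_samples = 20, n_probes = 1000, spikes = list(
    spike_spec(2, island = 1, f = 1, lambda = 0.7)), seed = 99)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_true(all(sim1$beta >= 0 & sim1$beta <= 1))
  expect_identical(sim1$beta, sim2$beta)
  expect_identical(sim1$manifest, sim2$manifest)
  # byte-identical artifacts on disk
  t1 <- tempfile(); t2 <- tempfile()
  write_beta_matrix(sim1$beta, t1)
  write_beta_matrix(sim2$beta, t2)
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("spiked cells track the expected beta at high concentration", {
  # one 500-probe island gives 500 spiked draws in a single cohort
  for (s in c(100, 150)) {
    cfg <- sim_config(n_samples = 5, n_probes = 1000, prop_island = 0.5,
                      prop_shore = 0.1, prop_opensea = 0.4,
                      island_size = 500, concentration = s,
                      spikes = list(spike_spec(1, island = 1, f = 1,
                                               lambda = 0.7)),
                      seed = 7)
    sim <- simulate_cohort(cfg)
    probes <- strsplit(sim$truth$probe_ids, ",")[[1]]
    expect_length(probes, 500)
    emp <- mean(sim$beta["S01", probes])
    expect_lt(abs(emp - sim$truth$expected_beta), 0.03)
  }
})

test_that("manifest positions increase within chromosomes and islands align", {
  cfg <- sim_config(n_probes = 2000, seed = 2)
  sim <- simulate_cohort(cfg)
  for (ch in unique(sim$manifest$chrom)) {
    expect_true(all(diff(sim$manifest$pos[sim$manifest$chrom == ch]) > 0))
  }
  # every island interval covers exactly its member probes (half-open)
  for (k in seq_len(min(5, nrow(sim$islands)))) {
    isl <- sim$islands[k, ]
    members <- sim$manifest[!is.na(sim$manifest$island_id) &
                              sim$manifest$island_id == isl$name, ]
    expect_true(all(members$chrom == isl$chrom))
    expect_true(all(members$pos > isl$start & members$pos <= isl$end))
  }
})

test_that("a spike straddling chromosomes is rejected", {
  cfg <- sim_config(n_probes = 2000, seed = 2)
  layout_probes <- simulate_cohort(cfg)$manifest
  chr1 <- layout_probes$probe_id[layout_probes$chrom == "chr1"]
  chr2 <- layout_probes$probe_id[layout_probes$chrom == "chr2"]
  bad <- sim_config(n_probes = 2000, seed = 2, spikes = list(
    spike_spec(1, probes = c(tail(chr1, 2), head(chr2, 2)))))
  expect_error(simulate_cohort(bad), "chromosome")
})

test_that("expression coupling has the designed sign and strength", {
  cfg0 <- sim_config(n_samples = 30, n_probes = 500, expr_sigma = 0,
                     expr_slope = 5, seed = 3)
  sim <- simulate_cohort(cfg0)
  probes <- sim$manifest$probe_id[!is.na(sim$manifest$island_id) &
                                    sim$manifest$island_id == "CGI001"]
  mb <- rowMeans(sim$beta[, probes])
  expr <- simulate_expression(sim$beta, probes, cfg0)
  for (p in seq_len(nrow(expr$values))) {
    expect_equal(cor(mb, expr$values[p, ]), -1)
  }
  # sign symmetry: negative slope means positive correlation
  cfg_neg <- sim_config(n_samples = 30, n_probes = 500, expr_sigma = 0,
                        expr_slope = -5, seed = 3)
  expr_neg <- simulate_expression(sim$beta, probes, cfg_neg)
  expect_equal(cor(mb, expr_neg$values[1, ]), 1)
})

test_that("uncoupled expression is null-correlated with methylation", {
  cfg <- sim_config(n_samples = 46, n_probes = 500, expr_slope = 0,
                    expr_sigma = 0.5, seed = 1)
  sim <- simulate_cohort(cfg)
  probes <- sim$manifest$probe_id[!is.na(sim$manifest$island_id) &
                                    sim$manifest$island_id == "CGI001"]
  mb <- rowMeans(sim$beta[, probes])
  rs <- vapply(1:20, function(k) {
    e <- simulate_expression(sim$beta, probes, cfg, seed = 1000 + k)
    cor(mb, e$values[1, ])
  }, numeric(1))
  n <- length(mb)
  expect_lt(abs(mean(rs)), 3 / sqrt(n) / sqrt(length(rs)) + 0.05)
  expect_true(all(abs(rs) < 4.5 / sqrt(n)))  # ~6 sigma under the null
  expect_error(simulate_expression(sim$beta, probes,
                                   sim_config(expr_k = 0)), "expr_k")
})

test_that("boundary variant table brackets every filter threshold", {
  vt6 <- simulate_variant_table(6)
  expect_identical(sort(vt6$consequence_class),
                   sort(c("frameshift", "stop_gain", "canonical_splice",
                          "start_loss", "missense", "other")))
  vt <- simulate_variant_table(18)
  expect_identical(vt, simulate_variant_table(18))  # deterministic
  maf <- round(100 * vt$control_ac / vt$control_an, 4)
  expect_setequal(maf, c(0.09, 0.10, 0.11))
  expect_setequal(vt$revel[vt$consequence_class == "missense"],
                  c(0.64, 0.65))
})
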
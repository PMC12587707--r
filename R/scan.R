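# The screening procedure: for every individual, every CpG beta value is
# compared to the beta values of the remaining cohort members with a
# single-case (Crawford-Howell-style) t statistic,
#     t = (x - mean_rest) / (sd_rest * sqrt(1 + 1/n_rest)),  df = n_rest - 1,
# which is algebraically the pooled-variance two-sample t with group sizes
# 1 and n_rest. Two-sided p values are BH-adjusted per individual, and an
# epimutation region is a maximal run of >= min_run consecutive testable
# probes (genomic order, one chromosome, consistent direction) all with
# q below the threshold.

#' Single-case outlier test of one sample against the rest of the cohort
#'
#' @param beta samples x probes beta matrix.
#' @param sample sample id or index to test.
#' @param probes probe ids to test (default: all columns).
#' @param min_rest_n minimum non-missing rest-of-cohort values for a probe
#'   to be testable; untestable probes yield NA statistics.
#' @param sd_floor lower bound applied to the rest standard deviation so a
#'   zero-variance reference group yields a finite, extreme statistic.
#' @return data.frame with one row per probe: `sample`, `probe`,
#'   `beta_self`, `rest_mean`, `rest_sd`, `n_rest`, `t_stat`, `df`, `p`,
#'   `q` (NA here; filled by [scan_cohort()]), `direction`.
#' @export
single_case_test <- function(beta, sample, probes = NULL, min_rest_n = 10L,
                             sd_floor = 1e-6) {
  if (is.numeric(sample)) sample <- rownames(beta)[sample]
  if (!sample %in% rownames(beta)) stop("unknown sample: ", sample)
  i <- match(sample, rownames(beta))
  pre <- .cohort_moments(beta)
  res <- .outlier_stats(beta, i, pre, min_rest_n = min_rest_n,
                        sd_floor = sd_floor)
  if (!is.null(probes)) {
    missing_probes <- setdiff(probes, res$probe)
    if (length(missing_probes) > 0L) {
      stop("unknown probe(s): ", paste(head(missing_probes, 5),
                                       collapse = ", "))
    }
    res <- res[match(probes, res$probe), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

# cohort-level sums reused across the per-sample loop
.cohort_moments <- function(beta) {
  list(nobs = colSums(!is.na(beta)),
       S = colSums(beta, na.rm = TRUE),
       Q = colSums(beta * beta, na.rm = TRUE))
}

# Rest-of-cohort sum of squares about the rest mean via the expansion
# sum((x - m)^2) = Q - 2 m S + n m^2 anchored at the rest mean. For beta
# values in [0,1] with realistic probe variance the cancellation error is
# negligible; truly degenerate (zero-variance) columns fall onto the sd
# floor anyway.
.outlier_stats_vec <- function(beta, i, pre, min_rest_n, sd_floor) {
  x <- beta[i, ]
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  n_rest <- as.integer(pre$nobs - obs)
  rest_S <- pre$S - x0
  rest_Q <- pre$Q - x0 * x0
  rest_mean <- rest_S / n_rest
  ss <- rest_Q - 2 * rest_mean * rest_S + n_rest * rest_mean^2
  rest_var <- pmax(ss, 0) / (n_rest - 1L)
  rest_sd <- pmax(sqrt(rest_var), sd_floor)
  t_stat <- (x - rest_mean) / (rest_sd * sqrt(1 + 1 / n_rest))
  df <- n_rest - 1L
  p <- 2 * pt(-abs(t_stat), df)
  untestable <- !obs | n_rest < min_rest_n
  t_stat[untestable] <- NA_real_
  p[untestable] <- NA_real_
  direction <- rep(NA_character_, length(x))
  ok <- !is.na(t_stat)
  direction[ok] <- c("hypo", "hyper")[(x[ok] > rest_mean[ok]) + 1L]
  list(beta_self = unname(x), rest_mean = unname(rest_mean),
       rest_sd = unname(rest_sd), n_rest = unname(n_rest),
       t_stat = unname(t_stat), df = unname(df), p = unname(p),
       direction = direction)
}

# Whole-cohort statistics in one pass: every (sample, probe) cell tested
# against the rest of its column. Returns samples x probes matrices.
.scan_stats_matrix <- function(beta, min_rest_n, sd_floor) {
  ns <- nrow(beta); np <- ncol(beta)
  obs <- !is.na(beta)
  X0 <- beta
  X0[!obs] <- 0
  nobs <- colSums(obs)
  S <- colSums(X0)
  Q <- colSums(X0 * X0)
  Nrest <- matrix(rep(nobs, each = ns), ns) - obs
  RS <- matrix(rep(S, each = ns), ns) - X0
  RQ <- matrix(rep(Q, each = ns), ns) - X0 * X0
  RM <- RS / Nrest
  ss <- RQ - 2 * RM * RS + Nrest * RM * RM
  RSD <- pmax(sqrt(pmax(ss, 0) / (Nrest - 1L)), sd_floor)
  t_stat <- (beta - RM) / (RSD * sqrt(1 + 1 / Nrest))
  p <- 2 * pt(-abs(t_stat), Nrest - 1L)
  untest <- !obs | Nrest < min_rest_n
  t_stat[untest] <- NA_real_
  p[untest] <- NA_real_
  list(t = t_stat, p = p, rest_mean = RM, rest_sd = RSD, n_rest = Nrest)
}

.outlier_stats <- function(beta, i, pre, min_rest_n, sd_floor) {
  v <- .outlier_stats_vec(beta, i, pre, min_rest_n, sd_floor)
  data.frame(
    sample = rownames(beta)[i],
    probe = colnames(beta),
    beta_self = v$beta_self,
    rest_mean = v$rest_mean,
    rest_sd = v$rest_sd,
    n_rest = v$n_rest,
    t_stat = v$t_stat,
    df = v$df,
    p = v$p,
    q = NA_real_,
    direction = v$direction,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up FDR adjustment over the non-missing p values; NAs stay NA and do
#' not count toward the number of tests.
#'
#' @param p numeric vector of p values (NAs allowed).
#' @return q values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must be in [0,1]")
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Classification thresholds for hypermethylated regions
#'
#' Calibrated so that a carrier mean beta of ~0.34 over a near-zero baseline
#' reads as constitutional monoallelic methylation and ~0.18 as mosaic,
#' matching the interpretation applied to such events in blood arrays.
#'
#' @param baseline_max max rest-of-cohort mean beta for a region to be a
#'   candidate epimutation over an unmethylated baseline.
#' @param mosaic_min,mono_min,mono_max carrier mean beta cut points:
#'   `[mono_min, mono_max]` = monoallelic, `[mosaic_min, mono_min)` =
#'   mosaic, below `mosaic_min` = low_level.
#' @return named list of thresholds.
#' @export
classify_thresholds <- function(baseline_max = 0.10, mosaic_min = 0.10,
                                mono_min = 0.25, mono_max = 0.60) {
  list(baseline_max = baseline_max, mosaic_min = mosaic_min,
       mono_min = mono_min, mono_max = mono_max)
}

# vectorized classification core
.classify_beta <- function(carrier, rest, direction,
                           th = classify_thresholds()) {
  ifelse(direction == "hypo", "hypomethylated",
  ifelse(rest >= th$baseline_max | carrier > th$mono_max, "hypermethylated",
  ifelse(carrier >= th$mono_min, "monoallelic",
  ifelse(carrier >= th$mosaic_min, "mosaic", "low_level"))))
}

#' Classify epimutation regions as monoallelic, mosaic or low-level
#'
#' Applies to hypermethylated regions over an unmethylated baseline
#' (rest mean beta below `baseline_max`): carrier mean beta in
#' `[mono_min, mono_max]` is called monoallelic (one allele methylated in
#' essentially all cells, attenuated by the array), `[mosaic_min, mono_min)`
#' mosaic (one allele methylated in a cell fraction), below `mosaic_min`
#' low_level. Hypomethylated regions pass through as "hypomethylated";
#' hyper regions over a methylated baseline or beyond the monoallelic band
#' are labelled "hypermethylated".
#'
#' @param regions region data.frame with `mean_beta_carrier`,
#'   `mean_beta_rest`, `direction` columns (as from [call_regions()]).
#' @param thresholds [classify_thresholds()].
#' @return character vector of labels, one per region.
#' @export
classify_region <- function(regions, thresholds = classify_thresholds()) {
  if (nrow(regions) == 0L) return(character(0))
  .classify_beta(regions$mean_beta_carrier, regions$mean_beta_rest,
                 regions$direction, thresholds)
}

#' Call epimutation regions from per-probe outlier results
#'
#' Probes are placed in genomic order (fixed chromosome order, then
#' position); a region is a maximal run of testable probes on one
#' chromosome, all with `q < q_threshold`, sharing a direction, with
#' consecutive-probe gaps of at most `max_gap` bp; runs shorter than
#' `min_run` are discarded. Region coordinates are 0-based half-open,
#' spanning the first to last member CpG.
#'
#' @param results outlier results with `q` filled (rows from one or more
#'   samples; see [single_case_test()] and [adjust_fdr()]).
#' @param manifest [probe_manifest()]; every result probe must be present.
#' @param min_run minimum CpGs per region (default 3).
#' @param q_threshold FDR threshold (default 0.005).
#' @param max_gap maximum bp between consecutive member probes (default
#'   unlimited).
#' @param thresholds classification thresholds, see [classify_thresholds()].
#' @return data.frame: `sample`, `chrom`, `start`, `end`, `probe_ids`
#'   (comma-separated), `n_probes`, `mean_beta_carrier`, `mean_beta_rest`,
#'   `min_q`, `max_q`, `direction`, `islands` (empty, see
#'   [annotate_islands()]), `classification`.
#' @export
call_regions <- function(results, manifest, min_run = 3L,
                         q_threshold = 0.005, max_gap = Inf,
                         thresholds = classify_thresholds()) {
  missing_probes <- setdiff(results$probe, manifest$probe_id)
  if (length(missing_probes) > 0L) {
    stop("probe(s) absent from manifest: ",
         paste(head(missing_probes, 5), collapse = ", "))
  }
  idx <- match(results$probe, manifest$probe_id)
  chrom <- manifest$chrom[idx]
  pos <- manifest$pos[idx]
  chord <- match(chrom, chrom_levels(chrom))
  empty <- data.frame(
    sample = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), probe_ids = character(0), n_probes = integer(0),
    mean_beta_carrier = numeric(0), mean_beta_rest = numeric(0),
    min_q = numeric(0), max_q = numeric(0), direction = character(0),
    islands = character(0), classification = character(0),
    stringsAsFactors = FALSE)
  keep <- which(!is.na(results$q))
  if (length(keep) == 0L) return(empty)
  # one global ordering: sample, then genomic order of testable probes
  o <- keep[order(results$sample[keep], chord[keep], pos[keep],
                  method = "radix")]
  sam <- results$sample[o]; ch <- chord[o]; chn <- chrom[o]; po <- pos[o]
  qq <- results$q[o]; dir <- results$direction[o]
  bs <- results$beta_self[o]; rm_ <- results$rest_mean[o]
  pid <- results$probe[o]
  sig <- qq < q_threshold
  n <- length(o)
  brk <- if (n > 1L) {
    c(TRUE, sam[-1L] != sam[-n] | ch[-1L] != ch[-n] |
        sig[-1L] != sig[-n] | dir[-1L] != dir[-n] |
        (po[-1L] - po[-n]) > max_gap)
  } else TRUE
  brk[is.na(brk)] <- TRUE  # direction is NA only on untestable rows
  starts <- which(brk)
  ends <- c(starts[-1L] - 1L, n)
  qual <- which(sig[starts] & (ends - starts + 1L) >= min_run)
  if (length(qual) == 0L) return(empty)
  regions <- do.call(rbind, lapply(qual, function(k) {
    rows <- starts[k]:ends[k]
    data.frame(
      sample = sam[starts[k]], chrom = chn[starts[k]],
      start = po[rows[1L]] - 1, end = po[rows[length(rows)]],
      probe_ids = paste(pid[rows], collapse = ","),
      n_probes = length(rows),
      mean_beta_carrier = mean(bs[rows]),
      mean_beta_rest = mean(rm_[rows]),
      min_q = min(qq[rows]), max_q = max(qq[rows]),
      direction = dir[starts[k]], islands = "",
      classification = NA_character_, stringsAsFactors = FALSE)
  }))
  regions$classification <- classify_region(regions, thresholds)
  rownames(regions) <- NULL
  regions
}

#' Attach overlapping CpG-island names to regions
#'
#' Any overlap of at least 1 bp (half-open interval semantics: a region
#' ending where an island starts does not overlap it) attaches the island
#' name; multiple overlaps are all attached, sorted, semicolon-separated.
#'
#' @param regions region data.frame from [call_regions()].
#' @param islands [island_set()].
#' @return `regions` with the `islands` column filled.
#' @export
annotate_islands <- function(regions, islands) {
  if (nrow(regions) == 0L || is.null(islands) || nrow(islands) == 0L) {
    return(regions)
  }
  rg <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  ig <- .islands_to_granges(islands)
  hits <- GenomicRanges::findOverlaps(rg, ig)
  nm <- split(islands$name[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  regions$islands <- ""
  for (k in names(nm)) {
    regions$islands[as.integer(k)] <- paste(sort(unique(nm[[k]])),
                                            collapse = ";")
  }
  regions
}

#' Screen a whole cohort for constitutional epimutations
#'
#' Runs the per-sample single-case test at every testable probe, adjusts p
#' values per sample (BH), calls consecutive-probe regions, annotates CpG
#' islands and classifies each region.
#'
#' @param beta samples x probes beta matrix (>= 12 samples so the reference
#'   group keeps at least 11 members).
#' @param manifest [probe_manifest()] covering the probes.
#' @param islands optional [island_set()] for annotation.
#' @param q_threshold per-sample FDR threshold (default 0.005).
#' @param min_run minimum consecutive CpGs per region (default 3).
#' @param max_gap maximum bp gap between member CpGs (default unlimited).
#' @param min_rest_n minimum non-missing reference values per probe.
#' @param thresholds classification thresholds, see [classify_thresholds()].
#' @return an object of class `epi_scan`: list with `regions` (data.frame),
#'   `per_sample` (region tally), `params`, `n_samples`, `n_probes`,
#'   `n_untestable`.
#' @export
scan_cohort <- function(beta, manifest, islands = NULL,
                        q_threshold = 0.005, min_run = 3L, max_gap = Inf,
                        min_rest_n = 10L,
                        thresholds = classify_thresholds()) {
  if (nrow(beta) < 12L) {
    stop("need at least 12 samples (reference group of >= 11)")
  }
  missing_probes <- setdiff(colnames(beta), manifest$probe_id)
  if (length(missing_probes) > 0L) {
    stop("probe(s) absent from manifest: ",
         paste(head(missing_probes, 5), collapse = ", "))
  }
  # genomic order of the probes actually present (manifest is pre-sorted)
  probe_order <- manifest$probe_id[manifest$probe_id %in% colnames(beta)]
  beta <- beta[, probe_order, drop = FALSE]
  midx <- match(probe_order, manifest$probe_id)
  chrom <- manifest$chrom[midx]
  chord <- match(chrom, chrom_levels(chrom))
  pos <- manifest$pos[midx]

  ns <- nrow(beta)
  np <- ncol(beta)
  st <- .scan_stats_matrix(beta, min_rest_n = min_rest_n, sd_floor = 1e-6)
  n_untestable <- sum(is.na(st$p))
  # positions where a run may not continue, shared across samples
  chain_brk <- if (np > 1L) {
    c(TRUE, chord[-1L] != chord[-np] | (pos[-1L] - pos[-np]) > max_gap)
  } else TRUE
  reg_list <- list()
  for (i in seq_len(ns)) {
    q <- adjust_fdr(st$p[i, ])
    testable <- which(!is.na(q))
    if (length(testable) == 0L) next
    sig <- q[testable] < q_threshold
    dirn <- sign(st$t[i, testable])
    m <- length(testable)
    brk <- if (m > 1L) {
      # any skipped untestable probe does not break adjacency; chromosome
      # change or an oversized gap between retained neighbours does
      gap_brk <- chord[testable[-1L]] != chord[testable[-m]] |
        (pos[testable[-1L]] - pos[testable[-m]]) > max_gap
      c(TRUE, gap_brk | sig[-1L] != sig[-m] | dirn[-1L] != dirn[-m])
    } else TRUE
    starts <- which(brk)
    ends <- c(starts[-1L] - 1L, m)
    qual <- which(sig[starts] & (ends - starts + 1L) >= min_run)
    for (k in qual) {
      rows <- testable[starts[k]:ends[k]]
      reg_list[[length(reg_list) + 1L]] <- data.frame(
        sample = rownames(beta)[i], chrom = chrom[rows[1L]],
        start = pos[rows[1L]] - 1, end = pos[rows[length(rows)]],
        probe_ids = paste(probe_order[rows], collapse = ","),
        n_probes = length(rows),
        mean_beta_carrier = mean(beta[i, rows]),
        mean_beta_rest = mean(st$rest_mean[i, rows]),
        min_q = min(q[rows]), max_q = max(q[rows]),
        direction = if (dirn[starts[k]] > 0) "hyper" else "hypo",
        islands = "", classification = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(reg_list) > 0L) {
    do.call(rbind, reg_list)
  } else {
    data.frame(
      sample = character(0), chrom = character(0), start = numeric(0),
      end = numeric(0), probe_ids = character(0), n_probes = integer(0),
      mean_beta_carrier = numeric(0), mean_beta_rest = numeric(0),
      min_q = numeric(0), max_q = numeric(0), direction = character(0),
      islands = character(0), classification = character(0),
      stringsAsFactors = FALSE)
  }
  regions$classification <- classify_region(regions, thresholds)
  if (nrow(regions) > 0L) {
    regions <- regions[order(regions$sample,
                             match(regions$chrom, chrom_levels(regions$chrom)),
                             regions$start, method = "radix"), , drop = FALSE]
  }
  rownames(regions) <- NULL
  if (!is.null(islands)) regions <- annotate_islands(regions, islands)
  per_sample <- data.frame(sample = rownames(beta),
                           n_regions = as.integer(
                             table(factor(regions$sample,
                                          levels = rownames(beta)))),
                           stringsAsFactors = FALSE)
  structure(list(
    regions = regions, per_sample = per_sample,
    params = list(q_threshold = q_threshold, min_run = min_run,
                  max_gap = max_gap, min_rest_n = min_rest_n,
                  thresholds = thresholds),
    n_samples = nrow(beta), n_probes = ncol(beta),
    n_untestable = n_untestable), class = "epi_scan")
}

#' @export
print.epi_scan <- function(x, ...) {
  cat("Constitutional epimutation scan\n")
  cat(sprintf("  cohort: %d samples x %d probes (%d untestable sample-probe cells)\n",
              x$n_samples, x$n_probes, x$n_untestable))
  cat(sprintf("  parameters: q < %g, min_run = %d, max_gap = %s\n",
              x$params$q_threshold, x$params$min_run,
              ifelse(is.finite(x$params$max_gap),
                     format(x$params$max_gap), "unlimited")))
  cat(sprintf("  regions called: %d in %d sample(s)\n", nrow(x$regions),
              length(unique(x$regions$sample))))
  if (nrow(x$regions) > 0L) {
    tab <- table(x$regions$classification)
    cat("  classification:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.epi_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.epi_scan")
}

#' @export
print.summary.epi_scan <- function(x, ...) {
  print(x$scan)
  reg <- x$scan$regions
  if (nrow(reg) > 0L) {
    cat("\nRegions:\n")
    print(reg[, c("sample", "chrom", "start", "end", "n_probes",
                  "mean_beta_carrier", "mean_beta_rest", "direction",
                  "islands", "classification")], row.names = FALSE)
  }
  carriers <- x$scan$per_sample[x$scan$per_sample$n_regions > 0L, ,
                                drop = FALSE]
  if (nrow(carriers) > 0L) {
    cat("\nSamples with regions:\n")
    print(carriers, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.epi_scan <- function(x, ...) x$regions
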
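# Expression-association stage: summarize a gene's expression probes as a
# rescaled first principal component, correlate per-CpG methylation with
# that summary (Pearson r, two-sided t), and contrast tumor vs paired
# normal methylation per probe.

#' First-principal-component summary of a gene's expression probes
#'
#' PC1 of the probes x samples matrix after per-probe centering. The score
#' sign is oriented so PC1 correlates positively with the probe of highest
#' standard deviation, and the scores are affinely rescaled to that probe's
#' mean and standard deviation, so the summary reads in the expression
#' units of the most variable probe. With a single probe the summary equals
#' that probe's values exactly.
#'
#' @param values expression probes x samples numeric matrix (no missing
#'   values; >= 3 samples).
#' @return named per-sample score vector.
#' @export
expression_pc1 <- function(values) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) < 3L) stop("need at least 3 samples")
  if (anyNA(values)) stop("expression matrix must have no missing values")
  probe_sd <- apply(values, 1L, sd)
  if (all(probe_sd == 0)) stop("zero total variance across expression probes")
  pc <- prcomp(t(values), center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1L]
  top <- which.max(probe_sd)
  ref <- values[top, ]
  if (cor(scores, ref) < 0) scores <- -scores
  out <- mean(ref) + sd(ref) * (scores - mean(scores)) / sd(scores)
  setNames(out, colnames(values))
}

#' Pearson correlation of per-CpG methylation with an expression score
#'
#' @param x beta values for one CpG across samples.
#' @param y expression score across the same samples.
#' @param probe label carried into the result.
#' @return one-row data.frame: `probe`, `r`, `n`, `t_stat`, `p`, `slope`,
#'   `intercept`. Zero variance in either vector gives an NA result with a
#'   warning; |r| = 1 yields p = 0.
#' @export
correlate_methylation_expression <- function(x, y, probe = NA_character_) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  na_row <- data.frame(probe = probe, r = NA_real_, n = n,
                       t_stat = NA_real_, p = NA_real_, slope = NA_real_,
                       intercept = NA_real_, stringsAsFactors = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined",
            if (!is.na(probe)) paste0(" (", probe, ")") else "")
    return(na_row)
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    r <- sign(r)
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  slope <- r * sd(y) / sd(x)
  data.frame(probe = probe, r = r, n = n, t_stat = t_stat, p = p,
             slope = slope, intercept = mean(y) - slope * mean(x),
             stringsAsFactors = FALSE)
}

#' Correlate several CpGs with an expression score
#'
#' @param beta samples x probes beta matrix.
#' @param probes CpG probe ids (columns of `beta`).
#' @param score per-sample expression summary, aligned to `rownames(beta)`.
#' @return data.frame, one [correlate_methylation_expression()] row per CpG.
#' @export
correlate_cpgs <- function(beta, probes, score) {
  missing_probes <- setdiff(probes, colnames(beta))
  if (length(missing_probes) > 0L) {
    stop("probe(s) absent from beta matrix: ",
         paste(head(missing_probes, 5), collapse = ", "))
  }
  if (!is.null(names(score))) score <- score[rownames(beta)]
  do.call(rbind, lapply(probes, function(pr) {
    suppressWarnings(
      correlate_methylation_expression(beta[, pr], score, probe = pr))
  }))
}

#' Paired tumor-vs-normal methylation contrast per probe
#'
#' Paired t test on per-pair deltas (tumor - normal) for each probe, with
#' probes ranked by |t|. A probe with all-zero deltas yields t = 0, p = 1;
#' zero delta variance with a nonzero mean yields an infinite t and p = 0.
#'
#' @param tumor,normal pairs x probes beta matrices with matching rows
#'   (same patient per row) and columns.
#' @param method `"t"` (default) or `"wilcoxon"` (signed-rank).
#' @return data.frame per probe: `probe`, `n_pairs`, `mean_tumor`,
#'   `mean_normal`, `mean_delta`, `t_stat`, `df`, `p`, `rank` (1 =
#'   strongest |t|, or smallest p for wilcoxon).
#' @export
paired_tumor_normal <- function(tumor, normal, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (!all(dim(tumor) == dim(normal))) {
    stop("tumor and normal matrices must have identical dimensions")
  }
  if (!is.null(colnames(tumor)) && !is.null(colnames(normal)) &&
      !identical(colnames(tumor), colnames(normal))) {
    stop("tumor and normal probe columns must match")
  }
  probes <- colnames(tumor)
  if (is.null(probes)) probes <- sprintf("probe_%d", seq_len(ncol(tumor)))
  rows <- lapply(seq_len(ncol(tumor)), function(j) {
    ok <- complete.cases(tumor[, j], normal[, j])
    tu <- tumor[ok, j]; no <- normal[ok, j]
    n <- length(tu)
    if (n < 3L) stop("need at least 3 complete pairs (probe ", probes[j], ")")
    d <- tu - no
    if (method == "t") {
      sdd <- sd(d)
      if (sdd == 0) {
        t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        p <- if (mean(d) == 0) 1 else 0
      } else {
        t_stat <- mean(d) / (sdd / sqrt(n))
        p <- 2 * pt(-abs(t_stat), df = n - 1)
      }
    } else {
      if (all(d == 0)) {
        t_stat <- 0; p <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = FALSE))
        t_stat <- unname(wt$statistic)
        p <- wt$p.value
      }
    }
    data.frame(probe = probes[j], n_pairs = n, mean_tumor = mean(tu),
               mean_normal = mean(no), mean_delta = mean(d),
               t_stat = t_stat, df = n - 1L, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- if (method == "t") -abs(out$t_stat) else out$p
  out$rank <- rank(key, ties.method = "min")
  out
}
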
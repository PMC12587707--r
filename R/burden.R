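# Rare-variant stage: the damaging-variant filter (consequence class, REVEL,
# population allele frequency) and the case-vs-control allele-frequency
# comparison on the filtered set.

#' Filter variants to the damaging / predicted-damaging set
#'
#' Rules, applied in this order to every record:
#' 1. drop any variant with population (control) MAF above `maf_threshold`
#'    percent, regardless of class;
#' 2. keep loss-of-function classes (frameshift, stop_gain, canonical_splice,
#'    start_loss) unconditionally;
#' 3. keep missense only if REVEL exceeds `revel_threshold` (missing REVEL
#'    drops the variant with a warning);
#' 4. drop class "other".
#'
#' @param variants [variant_table()].
#' @param maf_threshold population MAF cutoff in percent (default 0.1;
#'   variants strictly above it are removed).
#' @param revel_threshold REVEL cutoff (default 0.644; kept if strictly
#'   above).
#' @return the kept rows, same class; idempotent and order-invariant.
#' @export
filter_variants <- function(variants, maf_threshold = 0.1,
                            revel_threshold = 0.644) {
  maf_pct <- 100 * variants$control_ac / variants$control_an
  keep_maf <- maf_pct <= maf_threshold
  is_lof <- variants$consequence_class %in% .LOF_CLASSES
  is_mis <- variants$consequence_class == "missense"
  mis_norevel <- is_mis & is.na(variants$revel)
  if (any(mis_norevel & keep_maf)) {
    warning(sum(mis_norevel & keep_maf),
            " missense variant(s) without REVEL dropped")
  }
  keep_class <- is_lof |
    (is_mis & !is.na(variants$revel) & variants$revel > revel_threshold)
  out <- variants[keep_maf & keep_class, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allele frequency as a percentage
#'
#' `100 * alleles / (ploidy * n_individuals)`. In `"carriers"` mode the
#' count is heterozygous carrier individuals, each contributing one variant
#' allele. E.g. 4 carrier alleles in 632 individuals is 4/1264 = 0.32%.
#'
#' @param count variant allele count (or carrier count in carriers mode).
#' @param n_individuals individuals in the cohort.
#' @param ploidy alleles per individual at the locus (default 2).
#' @param mode `"alleles"` (default) or `"carriers"` (carriers map 1:1 to
#'   alleles).
#' @return frequency in percent, full precision.
#' @export
allele_frequency <- function(count, n_individuals, ploidy = 2,
                             mode = c("alleles", "carriers")) {
  mode <- match.arg(mode)
  if (any(n_individuals <= 0)) stop("n_individuals must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  100 * count / (ploidy * n_individuals)
}

#' Compare case vs control allele frequencies
#'
#' Builds the 2x2 allele table (variant / reference alleles by arm), reports
#' both MAFs in percent, the sample odds ratio (with the Haldane-Anscombe
#' 0.5 correction if and only if any cell is zero) and a two-sided Fisher
#' exact p value.
#'
#' @param case_ac,case_an case variant allele count and total allele number.
#' @param control_ac,control_an control counterpart.
#' @return object of class `burden_result` (named list).
#' @export
burden_compare <- function(case_ac, case_an, control_ac, control_an) {
  if (case_an <= 0 || control_an <= 0) stop("allele numbers must be positive")
  if (case_ac > case_an || control_ac > control_an) {
    stop("allele count exceeds allele number")
  }
  tab <- matrix(c(case_ac, case_an - case_ac,
                  control_ac, control_an - control_ac), nrow = 2)
  ct <- tab
  if (any(ct == 0)) ct <- ct + 0.5
  odds_ratio <- (ct[1, 1] / ct[2, 1]) / (ct[1, 2] / ct[2, 2])
  fisher_p <- fisher.test(tab)$p.value
  structure(list(
    case_ac = case_ac, case_an = case_an,
    control_ac = control_ac, control_an = control_an,
    case_maf = allele_frequency(case_ac, case_an, ploidy = 1),
    control_maf = allele_frequency(control_ac, control_an, ploidy = 1),
    odds_ratio = odds_ratio, fisher_p = fisher_p),
    class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Case vs control allele-frequency comparison\n")
  cat(sprintf("  cases:    %d/%d alleles (MAF = %.2f%%)\n",
              x$case_ac, x$case_an, x$case_maf))
  cat(sprintf("  controls: %d/%d alleles (MAF = %.2f%%)\n",
              x$control_ac, x$control_an, x$control_maf))
  cat(sprintf("  odds ratio = %.3f, two-sided Fisher p = %.3g\n",
              x$odds_ratio, x$fisher_p))
  invisible(x)
}

#' @export
as.data.frame.burden_result <- function(x, ...) {
  data.frame(case_ac = x$case_ac, case_an = x$case_an,
             control_ac = x$control_ac, control_an = x$control_an,
             case_maf = x$case_maf, control_maf = x$control_maf,
             odds_ratio = x$odds_ratio, fisher_p = x$fisher_p)
}
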
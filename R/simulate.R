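# Synthetic EPIC-like cohort generator. Background beta values are beta-
# distributed with a per-probe-class mean and a shared concentration
# (alpha = m*s, beta = (1-m)*s), which respects the [0,1] support and is the
# standard noise model for methylation fractions. Epimutations are spiked
# into chosen cells as a mixture of the unmethylated baseline and a
# methylated allele attenuated by the array:
#   e = (1 - f) * m + f * lambda * (0.5 + m/2)
# where f is the cellular fraction carrying the methylated allele (f = 1 for
# a constitutional monoallelic event, f < 1 for mosaicism) and lambda models
# the array's compression of true allelic methylation. With the defaults
# (m = 0.05, lambda = 0.7) a monoallelic spike reads ~0.37 and a mosaic
# spike with f = 0.35 reads ~0.22, inside the ranges observed on real
# arrays for such events.

#' Simulation configuration
#'
#' Defaults emulate a 46-sample EPIC-like screening cohort: CpG-island probes
#' near-unmethylated in blood (mean 0.05), shores intermediate (0.30), open
#' sea high (0.85), beta noise at concentration 150.
#'
#' @param n_samples cohort size.
#' @param n_probes probes on the simulated array.
#' @param prop_island,prop_shore,prop_opensea probe class mix; must sum to 1.
#' @param mean_island,mean_shore,mean_opensea baseline mean beta per class.
#' @param concentration beta-distribution concentration `s` (alpha+beta);
#'   larger = tighter probe noise.
#' @param island_size CpG probes per simulated island.
#' @param n_chrom chromosomes to spread probes over (chr1..chrN).
#' @param spikes list of [spike_spec()] entries.
#' @param expr_k,expr_slope,expr_sigma expression simulation: number of
#'   expression probes per gene, slope `b` of expression on mean region beta
#'   (positive = methylation represses), Gaussian noise sd.
#' @param seed RNG seed; same config + seed is bit-reproducible.
#' @return list classed `sim_config`.
#' @export
sim_config <- function(n_samples = 46, n_probes = 10000,
                       prop_island = 0.15, prop_shore = 0.15,
                       prop_opensea = 0.70,
                       mean_island = 0.05, mean_shore = 0.30,
                       mean_opensea = 0.85,
                       concentration = 150,
                       island_size = 5, n_chrom = 4,
                       spikes = list(),
                       expr_k = 3, expr_slope = 5, expr_sigma = 0.5,
                       seed = 1L) {
  props <- c(prop_island, prop_shore, prop_opensea)
  if (abs(sum(props) - 1) > 1e-8) stop("probe class proportions must sum to 1")
  if (any(props < 0)) stop("probe class proportions must be non-negative")
  if (concentration <= 0) stop("concentration must be positive")
  for (sp in spikes) {
    if (!inherits(sp, "spike_spec")) stop("spikes must be spike_spec() objects")
  }
  structure(list(
    n_samples = n_samples, n_probes = n_probes,
    prop_island = prop_island, prop_shore = prop_shore,
    prop_opensea = prop_opensea,
    mean_island = mean_island, mean_shore = mean_shore,
    mean_opensea = mean_opensea,
    concentration = concentration,
    island_size = island_size, n_chrom = n_chrom,
    spikes = spikes,
    expr_k = expr_k, expr_slope = expr_slope, expr_sigma = expr_sigma,
    seed = as.integer(seed)), class = "sim_config")
}

#' Specify one spiked epimutation
#'
#' @param sample carrier: sample index or id.
#' @param island island to methylate (index or name in the generated island
#'   set); alternatively give explicit `probes`.
#' @param probes explicit probe ids forming the block (optional).
#' @param f allelic/cellular fraction in (0, 1]; 1 = monoallelic in all
#'   cells, < 1 = mosaic.
#' @param lambda array attenuation in (0, 1].
#' @return list classed `spike_spec`.
#' @export
spike_spec <- function(sample, island = 1L, probes = NULL, f = 1,
                       lambda = 0.7) {
  if (f <= 0 || f > 1) stop("f must be in (0, 1]")
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  structure(list(sample = sample, island = island, probes = probes,
                 f = f, lambda = lambda), class = "spike_spec")
}

# expected array beta of a spiked cell
.spike_expected_beta <- function(f, lambda, m) {
  (1 - f) * m + f * lambda * (0.5 + m / 2)
}

# Genome layout: islands are cassettes of `island_size` consecutive island
# probes flanked by shore probes, embedded in open-sea filler; cassettes are
# split contiguously across chromosomes. Probe spacing is deterministic
# (100 bp in islands, 500 bp in shores, 2 kb open sea).
.cohort_layout <- function(config) {
  np <- config$n_probes
  isz <- config$island_size
  n_isl <- max(1L, round(np * config$prop_island / isz))
  shore_side <- max(0L, floor(np * config$prop_shore / (2 * n_isl)))
  per_unit_core <- isz + 2L * shore_side
  if (np < n_isl * per_unit_core) {
    stop("n_probes too small for the requested island/shore mix")
  }
  os_pre <- floor((np - n_isl * per_unit_core) / n_isl)
  unit <- c(rep("opensea", os_pre), rep("shore", shore_side),
            rep("island", isz), rep("shore", shore_side))
  cls <- rep(unit, n_isl)
  cls <- c(cls, rep("opensea", np - length(cls)))
  island_ordinal <- integer(np)
  island_ordinal[cls == "island"] <- rep(seq_len(n_isl), each = isz)

  # contiguous chromosome chunks aligned to cassette boundaries
  n_chrom <- min(config$n_chrom, n_isl)
  unit_chrom <- ceiling(seq_len(n_isl) * n_chrom / n_isl)
  probe_unit <- c(rep(seq_len(n_isl), each = length(unit)),
                  rep(n_isl, np - n_isl * length(unit)))
  chrom <- paste0("chr", unit_chrom[probe_unit])

  step <- c(island = 100L, shore = 500L, opensea = 2000L)[cls]
  pos <- integer(np)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- 10000L + cumsum(step[sel]) - step[sel][1L]
  }
  probe_id <- sprintf("cg%07d", seq_len(np))
  island_id <- ifelse(island_ordinal > 0L,
                      sprintf("CGI%03d", island_ordinal), NA_character_)
  manifest <- probe_manifest(data.frame(
    probe_id = probe_id, chrom = chrom, pos = pos, island_id = island_id,
    stringsAsFactors = FALSE))
  # manifest is sorted by (chrom, pos); recover per-probe class/means in
  # manifest order
  ord <- match(manifest$probe_id, probe_id)
  cls <- cls[ord]
  m <- c(island = config$mean_island, shore = config$mean_shore,
         opensea = config$mean_opensea)[cls]

  isl_rows <- which(!is.na(manifest$island_id))
  isl_split <- split(isl_rows, manifest$island_id[isl_rows])
  islands <- island_set(data.frame(
    chrom = vapply(isl_split, function(i) manifest$chrom[i[1L]], ""),
    start = vapply(isl_split, function(i) min(manifest$pos[i]) - 1L, 0),
    end = vapply(isl_split, function(i) max(manifest$pos[i]), 0),
    name = names(isl_split), stringsAsFactors = FALSE))
  list(manifest = manifest, islands = islands, class = cls, m = unname(m))
}

.resolve_spike <- function(sp, layout, sample_ids) {
  sample <- if (is.numeric(sp$sample)) sample_ids[sp$sample] else sp$sample
  if (!sample %in% sample_ids) stop("spike sample not in cohort: ", sp$sample)
  if (!is.null(sp$probes)) {
    probes <- sp$probes
    if (!all(probes %in% layout$manifest$probe_id)) {
      stop("spike probes absent from manifest")
    }
  } else {
    island <- sp$island
    if (is.numeric(island)) island <- layout$islands$name[island]
    probes <- layout$manifest$probe_id[
      !is.na(layout$manifest$island_id) & layout$manifest$island_id == island]
    if (length(probes) == 0L) stop("spike island not found: ", sp$island)
  }
  chroms <- unique(layout$manifest$chrom[
    match(probes, layout$manifest$probe_id)])
  if (length(chroms) > 1L) {
    stop("spike block spans multiple chromosomes: ",
         paste(chroms, collapse = ", "))
  }
  list(sample = sample, probes = probes)
}

#' Simulate an EPIC-like cohort with spiked epimutations
#'
#' @param config a [sim_config()].
#' @return list with `beta` (samples x probes matrix), `manifest`
#'   ([probe_manifest()]), `islands` ([island_set()]) and `truth`
#'   (data.frame: one row per spike with carrier sample, probe ids,
#'   expected beta and expected classification label).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  layout <- .cohort_layout(config)
  ns <- config$n_samples
  np <- nrow(layout$manifest)
  s <- config$concentration
  m <- layout$m
  sample_ids <- sprintf("S%02d", seq_len(ns))
  beta <- matrix(rbeta(ns * np, shape1 = rep(m * s, each = ns),
                       shape2 = rep((1 - m) * s, each = ns)),
                 nrow = ns, dimnames = list(sample_ids,
                                            layout$manifest$probe_id))
  truth <- data.frame(sample = character(0), probe_ids = character(0),
                      n_probes = integer(0), expected_beta = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  for (sp in config$spikes) {
    rs <- .resolve_spike(sp, layout, sample_ids)
    j <- match(rs$probes, colnames(beta))
    e <- .spike_expected_beta(sp$f, sp$lambda, m[j])
    beta[rs$sample, j] <- rbeta(length(j), e * s, (1 - e) * s)
    truth <- rbind(truth, data.frame(
      sample = rs$sample, probe_ids = paste(rs$probes, collapse = ","),
      n_probes = length(j), expected_beta = mean(e),
      label = .classify_beta(mean(e), mean(m[j]), "hyper",
                             classify_thresholds()),
      stringsAsFactors = FALSE))
  }
  list(beta = beta, manifest = layout$manifest, islands = layout$islands,
       truth = truth)
}

#' Simulate expression coupled to region methylation
#'
#' Each of `expr_k` expression probes for one gene is generated per sample as
#' `a_p - b * mean(region beta) + N(0, sigma^2)`, i.e. expression decreases
#' linearly with mean methylation of the region when `b > 0`.
#'
#' @param beta samples x probes beta matrix.
#' @param region_probes probe ids whose mean beta drives expression.
#' @param config [sim_config()] supplying `expr_k`, `expr_slope`,
#'   `expr_sigma`.
#' @param gene gene label for the probe map.
#' @param seed RNG seed (default derived from the config seed so the stage
#'   is reproducible standalone).
#' @return list with `values` (expression probes x samples matrix) and
#'   `probe_gene` (data.frame probe -> gene).
#' @export
simulate_expression <- function(beta, region_probes, config = sim_config(),
                                gene = "geneA", seed = config$seed + 1L) {
  k <- config$expr_k
  if (k < 1) stop("need at least one expression probe (expr_k >= 1)")
  missing_probes <- setdiff(region_probes, colnames(beta))
  if (length(missing_probes) > 0L) {
    stop("region probes absent from beta matrix: ",
         paste(head(missing_probes, 5), collapse = ", "))
  }
  set.seed(seed)
  mb <- rowMeans(beta[, region_probes, drop = FALSE], na.rm = TRUE)
  ns <- nrow(beta)
  a <- seq(7, 9, length.out = k)   # probe-specific baselines, arbitrary units
  values <- matrix(NA_real_, nrow = k, ncol = ns,
                   dimnames = list(sprintf("expr_%s_%02d", gene, seq_len(k)),
                                   rownames(beta)))
  for (p in seq_len(k)) {
    values[p, ] <- a[p] - config$expr_slope * mb +
      rnorm(ns, sd = config$expr_sigma)
  }
  list(values = values,
       probe_gene = data.frame(probe = rownames(values), gene = gene,
                               stringsAsFactors = FALSE))
}

#' Simulate a variant table straddling every filter boundary
#'
#' Emits a deterministic template of records designed to sit just on either
#' side of the damaging-variant filter rules: control MAF at 0.09% / 0.10% /
#' 0.11% (threshold: drop if > 0.1%) and REVEL 0.65 / 0.64 for missense
#' (threshold: keep if > 0.644), across all six consequence classes. The
#' first six records are one per consequence class.
#'
#' @param n_records rows to emit (cycled from the 18-row boundary template).
#' @param gene gene label.
#' @return [variant_table()] data.frame.
#' @export
simulate_variant_table <- function(n_records = 18L, gene = "LTBP4like") {
  classes <- .VARIANT_CLASSES
  an <- 10000L
  scen <- data.frame( # one scenario block per MAF boundary side
    control_ac = c(9L, 10L, 11L),       # 0.09%, 0.10%, 0.11%
    revel_missense = c(0.65, 0.64, 0.65))
  rows <- do.call(rbind, lapply(seq_len(nrow(scen)), function(i) {
    data.frame(
      gene = gene,
      id = sprintf("var_%02d", (i - 1L) * length(classes) + seq_along(classes)),
      consequence_class = classes,
      revel = ifelse(classes == "missense", scen$revel_missense[i], NA_real_),
      control_ac = scen$control_ac[i],
      control_an = an,
      case_carriers = 1L,
      stringsAsFactors = FALSE)
  }))
  idx <- rep_len(seq_len(nrow(rows)), n_records)
  out <- rows[idx, , drop = FALSE]
  out$id <- sprintf("var_%02d", seq_len(n_records))
  suppressWarnings(variant_table(out))
}
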
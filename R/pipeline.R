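# End-to-end wiring: simulate -> scan -> correlate -> burden, each stage
# runnable standalone on the previous stage's files, plus a manifest JSON
# with content hashes so a rerun with the same config + seed is verifiably
# identical. Every effective parameter (including defaults) is echoed into
# the manifest so the thresholds in force are auditable from the outputs.

#' Default pipeline configuration
#'
#' Nested named list covering every stage. Unknown keys in a user config are
#' a hard error (no silently ignored typos); all defaults are echoed into
#' the run manifest.
#'
#' @param ... top-level overrides (e.g. `seed = 7`, `scan = list(min_run = 4)`;
#'   nested lists are merged key-wise).
#' @return config list, classed `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    outdir = "epimutr_run",
    sim = list(
      n_samples = 46L, n_probes = 2000L,
      prop_island = 0.15, prop_shore = 0.15, prop_opensea = 0.70,
      mean_island = 0.05, mean_shore = 0.30, mean_opensea = 0.85,
      concentration = 150, island_size = 5L, n_chrom = 4L,
      spikes = list(
        list(sample = 1L, island = 1L, f = 1, lambda = 0.7),
        list(sample = 5L, island = 3L, f = 0.35, lambda = 1))),
    scan = list(q_threshold = 0.005, min_run = 3L, max_gap = Inf,
                min_rest_n = 10L),
    classify = list(baseline_max = 0.10, mosaic_min = 0.10,
                    mono_min = 0.25, mono_max = 0.60),
    expr = list(expr_k = 3L, expr_slope = 5, expr_sigma = 0.5),
    burden = list(maf_threshold = 0.1, revel_threshold = 0.644,
                  case_n = 632L, control_an = NULL, n_records = 18L))
  cfg <- .merge_config(defaults, list(...), path = "")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.merge_config <- function(base, override, path) {
  if (length(override) == 0L) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "")) stop("config entries must be named")
  unknown <- setdiff(nms, names(base))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in nms) {
    if (is.list(base[[k]]) && is.list(override[[k]]) && k != "spikes") {
      base[[k]] <- .merge_config(base[[k]], override[[k]],
                                 paste0(path, ".", k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys are validated against [pipeline_config()]; unknown keys are a hard
#' error.
#'
#' @param path YAML file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(pipeline_config, user)
}

.cfg_sim_config <- function(config) {
  spikes <- lapply(config$sim$spikes, function(sp) do.call(spike_spec, sp))
  sim_config(
    n_samples = config$sim$n_samples, n_probes = config$sim$n_probes,
    prop_island = config$sim$prop_island, prop_shore = config$sim$prop_shore,
    prop_opensea = config$sim$prop_opensea,
    mean_island = config$sim$mean_island, mean_shore = config$sim$mean_shore,
    mean_opensea = config$sim$mean_opensea,
    concentration = config$sim$concentration,
    island_size = config$sim$island_size, n_chrom = config$sim$n_chrom,
    spikes = spikes,
    expr_k = config$expr$expr_k, expr_slope = config$expr$expr_slope,
    expr_sigma = config$expr$expr_sigma,
    seed = config$seed)
}

.cfg_thresholds <- function(config) {
  do.call(classify_thresholds, config$classify)
}

#' Run the full pipeline
#'
#' Stages in order: simulate (cohort + truth table), scan (epimutation
#' regions TSV/BED + per-sample summary JSON), correlate (expression PC1 and
#' per-CpG correlation TSV for the first spiked region), burden (boundary
#' variant table, damaging filter, case-vs-control comparison). A failed
#' stage stops the run with a nonzero status; earlier outputs are retained.
#'
#' @param config [pipeline_config()], or a path to a YAML config.
#' @param outdir output directory (default from the config).
#' @param quiet suppress progress messages.
#' @return invisibly, list with `status` (0 = success), `manifest` (file
#'   list with md5 hashes) and `manifest_path`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(outdir)) outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  files <- character(0)
  status <- 0L
  failed_stage <- NULL
  path <- function(f) file.path(outdir, f)

  stages <- list(
    simulate = function() {
      sc <- .cfg_sim_config(config)
      sim <- simulate_cohort(sc)
      write_beta_matrix(sim$beta, path("beta.tsv"))
      write_manifest(sim$manifest, path("manifest.tsv"))
      write_islands(sim$islands, path("islands.bed"))
      write.table(sim$truth, path("truth.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <<- c(files, "beta.tsv", "manifest.tsv", "islands.bed",
                  "truth.tsv")
    },
    scan = function() {
      beta <- read_beta_matrix(path("beta.tsv"))
      manifest <- read_manifest(path("manifest.tsv"))
      islands <- read_islands(path("islands.bed"))
      fit <- scan_cohort(beta, manifest, islands,
                         q_threshold = config$scan$q_threshold,
                         min_run = config$scan$min_run,
                         max_gap = config$scan$max_gap,
                         min_rest_n = config$scan$min_rest_n,
                         thresholds = .cfg_thresholds(config))
      write_regions(fit$regions, tsv = path("regions.tsv"),
                    bed = path("regions.bed"))
      jsonlite::write_json(
        list(n_samples = fit$n_samples, n_probes = fit$n_probes,
             n_untestable = fit$n_untestable,
             per_sample = fit$per_sample, params = fit$params),
        path("scan_summary.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE, force = TRUE)
      files <<- c(files, "regions.tsv", "regions.bed", "scan_summary.json")
      say(sprintf("scan: %d region(s) called", nrow(fit$regions)))
    },
    correlate = function() {
      beta <- read_beta_matrix(path("beta.tsv"))
      truth <- read.table(path("truth.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      manifest <- read_manifest(path("manifest.tsv"))
      probes <- if (nrow(truth) > 0L) {
        strsplit(truth$probe_ids[1L], ",")[[1L]]
      } else {
        manifest$probe_id[!is.na(manifest$island_id) &
                            manifest$island_id == manifest$island_id[
                              which(!is.na(manifest$island_id))[1L]]]
      }
      sc <- .cfg_sim_config(config)
      expr <- simulate_expression(beta, probes, sc)
      df <- data.frame(probe = rownames(expr$values),
                       format(expr$values, digits = 15, trim = TRUE),
                       check.names = FALSE)
      write.table(df, path("expression.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      score <- expression_pc1(expr$values)
      ctab <- correlate_cpgs(beta, probes, score)
      write.table(ctab, path("correlations.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <<- c(files, "expression.tsv", "correlations.tsv")
      say(sprintf("correlate: mean r = %.3f over %d CpG(s)",
                  mean(ctab$r, na.rm = TRUE), nrow(ctab)))
    },
    burden = function() {
      vt <- simulate_variant_table(config$burden$n_records)
      write_variants(vt, path("variants.tsv"))
      kept <- filter_variants(vt,
                              maf_threshold = config$burden$maf_threshold,
                              revel_threshold = config$burden$revel_threshold)
      write_variants(kept, path("variants_kept.tsv"))
      case_ac <- sum(kept$case_carriers)
      case_an <- 2L * config$burden$case_n
      # control pool: explicit allele number from the config, else the
      # variant table's shared pool size
      control_an <- config$burden$control_an
      if (is.null(control_an)) control_an <- max(kept$control_an)
      br <- burden_compare(case_ac, case_an, sum(kept$control_ac), control_an)
      jsonlite::write_json(as.data.frame(br), path("burden.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      files <<- c(files, "variants.tsv", "variants_kept.tsv", "burden.json")
      say(sprintf("burden: %d/%d variant(s) kept, OR = %.3f",
                  nrow(kept), nrow(vt), br$odds_ratio))
    })

  for (stage in names(stages)) {
    ok <- tryCatch({ stages[[stage]](); TRUE },
                   error = function(e) {
                     message("stage '", stage, "' failed: ",
                             conditionMessage(e))
                     FALSE
                   })
    if (!ok) { status <- 1L; failed_stage <- stage; break }
  }

  hashes <- unname(tools::md5sum(file.path(outdir, files)))
  manifest <- list(
    package = "epimutr",
    version = as.character(packageVersion("epimutr")),
    seed = config$seed,
    status = status,
    failed_stage = failed_stage,
    config = unclass(config),
    files = data.frame(file = files, md5 = hashes,
                       stringsAsFactors = FALSE))
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       null = "null")
  invisible(list(status = status, manifest = manifest,
                 manifest_path = manifest_path))
}
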
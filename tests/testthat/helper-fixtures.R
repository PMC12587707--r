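# Small in-code fixtures shared across test files.

# beta matrix with named dims; values clipped into [0,1]
make_beta <- function(ns, np, seed = 1, mean = 0.5, sd = 0.1) {
  set.seed(seed)
  m <- matrix(pmin(pmax(rnorm(ns * np, mean, sd), 0), 1), nrow = ns,
              dimnames = list(sprintf("S%02d", seq_len(ns)),
                              sprintf("cg%05d", seq_len(np))))
  m
}

# manifest with np probes on one chromosome, evenly spaced
make_manifest <- function(np, chrom = "chr1", start = 1000L, step = 100L) {
  probe_manifest(data.frame(
    probe_id = sprintf("cg%05d", seq_len(np)),
    chrom = chrom,
    pos = start + step * (seq_len(np) - 1L),
    stringsAsFactors = FALSE))
}

# outlier-results rows for call_regions tests
make_results <- function(probes, q, direction = "hyper",
                         sample = "S01", beta_self = 0.4, rest_mean = 0.05) {
  data.frame(sample = sample, probe = probes, beta_self = beta_self,
             rest_mean = rest_mean, q = q, direction = direction,
             stringsAsFactors = FALSE)
}

# one full-scale spike-recovery run: 46 x 10000 cohort, one 5-probe
# monoallelic spike over island background 0.05 at concentration 150
spike_recovery_run <- function(seed) {
  cfg <- sim_config(
    n_samples = 46, n_probes = 10000, concentration = 150,
    spikes = list(spike_spec(sample = ((seed - 1) %% 46) + 1,
                             island = ((seed - 1) %% 30) + 1,
                             f = 1, lambda = 0.7)),
    seed = seed)
  sim <- simulate_cohort(cfg)
  fit <- scan_cohort(sim$beta, sim$manifest, sim$islands)
  truth_probes <- strsplit(sim$truth$probe_ids, ",")[[1]]
  reg <- fit$regions
  is_spike <- if (nrow(reg) == 0L) logical(0) else {
    reg$sample == sim$truth$sample &
      vapply(strsplit(reg$probe_ids, ","),
             function(p) sum(p %in% truth_probes) >= 3, logical(1))
  }
  c(hit = as.integer(any(is_spike)), fp = nrow(reg) - sum(is_spike))
}
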
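---
title: "Screening cohorts for constitutional epimutations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cohorts for constitutional epimutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimutr)
```

## The problem

A constitutional epimutation is aberrant methylation of a promoter or CpG
island present in an individual's normal tissues — detectable in blood —
rather than acquired somatically by a tumor. When it silences one allele of
a cancer predisposition gene it can phenocopy a germline pathogenic variant,
which makes it a candidate explanation for early-onset or familial cancer in
patients whose sequencing is negative. The screen implemented here takes a
cohort of such patients profiled on a β-value methylation array and asks,
for every individual and every CpG, whether that individual's methylation is
an outlier against the rest of the cohort, then aggregates per-CpG outliers
into regions and interprets their β levels.

Using the cohort itself as the reference population is what makes the design
work with no external controls: a constitutional epimutation is expected in
at most one (rarely a few) of several dozen unrelated patients, so the
"other n − 1" form an adequate normative sample at almost every locus.

## The outlier statistic

For sample $i$ at probe $j$, with rest-of-cohort mean $m_{(i)j}$, standard
deviation $s_{(i)j}$ and size $n$:

$$ t_{ij} = \frac{x_{ij} - m_{(i)j}}{s_{(i)j}\sqrt{1 + 1/n}}, \qquad
   \mathrm{df} = n - 1 $$

This is the single-case comparison statistic of Crawford and Howell,
algebraically identical to a pooled-variance two-sample t test with group
sizes 1 and $n$ (a property the test suite verifies to $10^{-10}$ against an
independently coded pooled oracle). We chose it because it is the standard
test of one observation against a normative sample, with well-defined
degrees of freedom; the screen's original description left the statistic
unnamed, so this is a repository decision, recorded here.

Numerical guards:

* the rest standard deviation is floored at $10^{-6}$, so a degenerate
  zero-variance reference yields a finite, extreme statistic rather than
  division by zero;
* rest moments are computed by a sum-of-squares expansion anchored at the
  rest mean; for β values in $[0,1]$ with realistic probe variance the
  cancellation error of this form is orders of magnitude below the $10^{-10}$
  oracle-agreement bound, and truly degenerate columns land on the sd floor;
* a probe is *testable* for a sample only if the rest group has at least
  `min_rest_n = 10` non-missing values (a variance estimate from fewer
  normative points is too unstable to support tail probabilities);
  untestable cells are counted and excluded, and they do not break probe
  adjacency for region calling.

Two-sided p values are used and the direction (hyper/hypo) recorded
separately: the events of interest are hypermethylations, but
hypomethylation is symmetric and costs nothing to retain.

## FDR control and region calling

p values are Benjamini–Hochberg adjusted **within each individual** across
all of that individual's testable probes, matching the per-patient framing
of the comparison ("this patient against the other n − 1"). Adjusting across
all individuals jointly would also be defensible; per-sample adjustment is
the default and the scope is deliberately explicit in the output manifest.
The q threshold is 0.005.

A region requires at least `min_run = 3` *consecutive* significant CpGs.
Consecutive means adjacent testable probes in genomic order — fixed
chromosome order (chr1..chr22, chrX, chrY, others last), then position —
on one chromosome, all sharing a direction. By default no limit is placed
on the base-pair gap between neighbours (`max_gap = Inf`), because probe
spacing already encodes array design density; a kilobase-scale cap can be
set where sparse open-sea probes would otherwise chain into implausible
regions. Region coordinates are 0-based half-open, spanning first to last
member CpG; island overlap (any shared base, half-open semantics) is
annotated from a BED interval set. Manifest positions are 1-based
(array-manifest convention); conversion to and from BED happens only at the
BED boundary, because mixing the two conventions mid-pipeline is the
classic DMR-caller bug.

Both knobs are monotone by construction — raising `min_run` or lowering the
q threshold can only remove regions — and the suite asserts this on
simulated cohorts.

## Interpreting region β levels

On an array, a fully monoallelic methylation event (one allele methylated in
essentially all cells) does not read β = 0.5: probe chemistry and
cross-hybridisation compress it, and observed constitutional monoallelic
events sit around β ≈ 0.26–0.42. Mosaic events — one allele methylated in a
fraction of cells — sit lower, around β ≈ 0.14–0.22 with pyrosequencing
confirming ~14% methylation. The classifier encodes exactly this reading:
for a hypermethylated region over a near-zero baseline (rest mean β < 0.10),
carrier mean β in [0.25, 0.60] is *monoallelic*, [0.10, 0.25) is *mosaic*,
below 0.10 *low_level*. The cut points are calibrated to the two observed
cases (0.34 → monoallelic, 0.18 → mosaic), exposed as configuration, and not
claimed to be more than a reading aid.

Two situations fall outside that scheme: a hyper region over an already
methylated baseline (rest mean ≥ 0.10), and a carrier mean beyond 0.60
(suggesting a biallelic or technical event). Rather than forcing either into
"low_level", both are labelled `hypermethylated` — a deliberate extension of
the label set so that no region is mislabelled as a low-grade epimutation
when it is nothing of the sort. Hypomethylated regions pass through as
`hypomethylated`.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: it defines
the study conditions under which the scan's operating characteristics are
measured.

* **Background noise.** β for probe $j$, sample $i$ is drawn from a Beta
  distribution parameterised by mean and concentration
  ($\alpha = m s$, $\beta = (1-m)s$), the standard respectful-of-support
  noise model for methylation fractions. Default class means are island
  0.05, shore 0.30, open sea 0.85 — canonical blood-array behaviour — with
  concentration $s = 150$ (per-probe sd ≈ 0.018 at the island baseline,
  matching the tight technical spread of EPIC island probes).
* **Spikes.** A spiked cell's expected value is
  $e = (1-f)\,m + f\,\lambda\,(0.5 + m/2)$, where $f$ is the cellular
  fraction carrying the methylated allele and $\lambda$ the array's
  attenuation of true allelic methylation. $\lambda = 0.7$ by default, so a
  fully monoallelic spike over $m = 0.05$ reads $e \approx 0.37$ — inside
  the observed monoallelic band — and $f = 0.35$ reads $e \approx 0.22$,
  near the observed mosaic case. The attenuation reproduces observed read
  levels without asserting a mechanism.
* **Layout.** Islands are cassettes of five consecutive island probes
  (100 bp spacing) flanked by shore probes inside open-sea filler, split
  contiguously across chromosomes; positions are deterministic, so
  "consecutive" is well defined and a fixed seed gives byte-identical
  artifacts.
* **Expression.** Each expression probe is
  $a_p - b\,\overline{\beta}_{\mathrm{region}} + \mathcal N(0,\sigma^2)$;
  with $b > 0$ methylation represses expression linearly. Defaults
  ($k = 3$ probes, $b = 5$, $\sigma = 0.5$) give correlations around −0.5
  to −0.8 at $n = 46$ — strong but noisy, like real island–expression
  coupling — and $\sigma = 0$ degenerates to $r = -1$ exactly.
* **Variants.** The boundary table is deterministic by design: every
  consequence class at control MAF 0.09% / 0.10% / 0.11% and missense REVEL
  0.65 / 0.64, bracketing the filter thresholds (MAF > 0.1% dropped;
  REVEL > 0.644 kept) on both sides, including the keep-at-exact-threshold
  MAF case.

What the generator does **not** emulate: probe type I/II chemistry bias,
batch and position effects, cell-composition shifts, sex chromosomes,
correlated probe noise within a region, and population structure in the
variant table. Passing tests therefore demonstrate the statistical machinery
under clean conditions — sensitivity ≥ 0.95 with ≤ 0.05 false regions per
cohort on 46 × 10,000 spiked cohorts — not robustness to those artefacts,
which upstream normalisation is assumed to have handled.

## Expression summary and correlation stage

A gene measured by several expression probes is summarised as the first
principal component of the per-probe-centred probe × sample matrix. The
published description of the rescaling ("reflect the average expression of
the probes with the highest observed standard deviation") is ambiguous; this
package orients the PC1 sign to correlate positively with the single
highest-SD probe and rescales the scores to that probe's mean and standard
deviation. That is the closest literal reading, it makes the one-probe case
an exact identity, and it is exposed as the documented behaviour rather than
hidden. Per-CpG Pearson correlations carry $t = r\sqrt{(n-2)/(1-r^2)}$ with
two-sided p at df = n − 2; $|r| = 1$ maps to p = 0 by continuity rather
than NA. Zero variance in either vector yields an NA result with a warning.

The tumor-vs-normal contrast is a paired t test on per-pair deltas (probes
ranked by |t|), chosen over Wilcoxon to match the parametric style of the
rest of the pipeline; a signed-rank alternative sits behind
`method = "wilcoxon"`. All-zero deltas give t = 0, p = 1; zero-variance
nonzero shifts give p = 0.

## Variant filter and burden comparison

Filtering order matters and is fixed: the population-frequency rule
(control MAF > 0.1% removed) applies to **all** classes first, then
loss-of-function classes (frameshift, stop-gain, canonical splice,
start-loss) are kept unconditionally, missense kept iff REVEL > 0.644,
class "other" dropped. Missense without a REVEL score cannot pass the
missense rule and is dropped with a warning.

The burden comparison reports MAFs as 100·AC/AN, a sample odds ratio with
the Haldane–Anscombe 0.5 correction applied iff any cell is zero, and a
two-sided Fisher exact p — chosen for exactness at the tiny case counts
involved; the suite checks it against full hypergeometric enumeration.
Carriers are assumed heterozygous (one variant allele each), so 4 carriers
among 632 individuals is 4/1264 alleles = 0.32%, and a control cohort of
590,031 diploid individuals contributes 1,180,062 alleles, giving
5,542/1,180,062 = 0.47%.

## Problem sizes and reproducibility

The spike-recovery characterisation uses 100 cohorts of 46 samples ×
10,000 probes — large enough that a 5-probe spike competes against ~10,000
BH-corrected tests per sample, small enough to re-run routinely (about a
minute on one CPU). Permutation cross-checks use $10^5$ shuffles; BH is
checked exhaustively against a step-up oracle on grids up to length 8;
Fisher enumeration covers tables with totals ≤ 200. Every stochastic step
takes an explicit seed, the pipeline writes md5 hashes of all artifacts,
and identical config + seed reproduces identical bytes.

## Known limitations

* The reference distribution is the cohort itself: two carriers of the same
  epimutation in one cohort inflate each other's reference variance and can
  mask each other — the known failure mode of leave-one-out outlier screens.
* β-scale testing (not M-values) is used throughout, matching how such
  screens are run and read; heteroscedasticity near the β boundaries is
  absorbed by the per-probe empirical variance but not modelled.
* Classification thresholds are calibrated to two observed cases; they are
  configuration, not biology.
* The burden stage consumes pre-annotated variant tables; consequence
  calling and REVEL scoring are upstream.
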
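---
title: "Comparing nCounter platform generations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing nCounter platform generations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocompare)
```

## The problem

When a laboratory upgrades its NanoString nCounter System — a new
PrepStation (the robotic liquid handler that purifies and immobilizes
probe–target complexes) and a new Digital Analyzer (the epifluorescence
scanner that counts color-coded barcodes) — the question is whether counts
produced before and after the upgrade can be pooled. `nanocompare`
implements a comparison framework for exactly this situation: a common set
of six biological samples is run in duplicate on four 12-lane cartridges
(A–D) that cross the two PrepStation generations with the two scanner
generations, and every cartridge is scanned twice:

| cartridge | PrepStation | scanner | FOV |
|-----------|-------------|---------|-----|
| A         | second gen  | second gen | 320 |
| B         | first gen   | first gen  | 600 |
| C         | second gen  | first gen  | 600 |
| D         | first gen   | second gen | 320 |

This gives 4 × 12 × 2 = 96 lane-scan observations per probe. The design is
balanced: every cartridge carries every sample in both replicates at both
scans, which is what makes the variance decomposition below orthogonal.

## Normalization

Raw RCC counts are normalized in three steps, in this order:

1. **Positive-control efficiency correction.** Each lane's factor is
   `mean over lanes of (geometric mean of positive counts) / this lane's
   geometric mean`, so that factor × lane geomean is constant across
   lanes.
2. **Negative-control background filtering.** The per-lane threshold is
   `mean(negatives) + k_sd × sd(negatives)` with `k_sd = 2` by default —
   the conventional nCounter background definition. Only endogenous
   features can be removed; the default keep rule (`majority_lanes`)
   retains a feature if it exceeds the lane threshold in at least half of
   the lanes. `any_lane` and `all_lanes` are available because the choice
   is not forced by anything in the data; the normalization report records
   which rule was used.
3. **Housekeeping median scaling.** Each lane's factor scales its median
   housekeeping count to the mean of the per-lane medians. We read
   "median normalization using housekeeping genes" as lane-median-of-
   housekeeping scaling, which honours both words of the phrase.

Finally values are transformed as `log2(x + 1)`; the +1 offset maps zero
counts to zero and is configurable (`log_offset`).

## Lane concordance

`pairwise_pcc()` pairs the lanes of two cartridges at a given scan by
(sample, replicate) position and computes the Pearson correlation across
all retained features — 12 correlations per cartridge pair on the standard
design. `scanpair_pcc()` does the same between the two scans of one
cartridge. Correlations are computed on log2 values; on well-behaved
technical replicates they sit above 0.99. Two-way hierarchical clustering
(`cluster_heatmap()`, Euclidean distance and average linkage by default;
both exposed) provides the qualitative companion: technical replicates of
the same biological sample should cluster together.

## Variance decomposition

The core of the package is a per-feature ANOVA. For each probe the log2
expression vector `y` over the relevant 48 observations is decomposed
under one of three models:

* **scan1** (first-scan data, all four cartridges):
  `y ~ mean + P + S + B + e` with P the PrepStation generation (1 df),
  S the scanner generation (1 df), B the biological sample (5 df), and a
  40-df residual driven by within-cartridge duplicates.
* **scan2** (second-scan data): `y ~ mean + PS + Cart + B + e`. At a
  single scan of this layout the prep and scanner generations are not
  separable from cartridges; `PS` is the prep+scanner *sum* coded as a
  three-level factor ({A} = both second generation, {B} = both first,
  {C, D} = mixed — under additivity C and D share the same sum), and
  `Cart` is the C-vs-D contrast nested in the mixed level (1 df), i.e. a
  pure between-cartridge replicate difference. This is the only coding in
  which PS, cartridge and sample are simultaneously estimable here
  (df 2, 1, 5; residual 39).
* **both_scans** (cartridges A and B at both scans):
  `y ~ mean + PS + T + B + e` with PS the A-vs-B (all-second vs all-first
  generation) contrast, T the scan-time effect, residual 40 df.

Sums of squares are sequential least-squares projections onto nested
design subspaces (features are centred first so the projections live on
the corrected scale); on the balanced design the terms are orthogonal, so
the sequential SS equal any classical SS type and do not depend on term
order. Each term is reported as df, SS, MS = SS/df and RMS = √MS. Features
are fitted independently — smoothing happens after fitting, never during —
and each model records the mean expression over its own observations as
the x-axis for the trend curves.

Tiny negative SS differences from floating-point cancellation are clamped
at zero; conservation (`SS_total = Σ SS_terms + SS_residual`) holds to
1e-8 relative and is asserted in the tests against an independent
`lm()`/`anova()` oracle.

## RMS trend curves

Per-feature RMS values are smoothed against mean log2 expression with
classical LOESS (`loess_smooth()`): at each grid point the
`ceiling(span × n)` nearest neighbours are tricube-weighted,
`w = (1 − (d/d_max)^3)^3`, and a local polynomial is fitted and evaluated.
Defaults are span 0.75 and degree 2 (the conventional LOESS defaults); no
robustness iterations. All sources of a model are evaluated on one common
grid — 100 points spanning the central 98% of mean expression, trimming
the sparse extremes where local windows become one-sided — so curves are
pointwise comparable.

One statistical subtlety matters here. An RMS on `df` degrees of freedom
is a biased estimator of its source's standard deviation:
`E[sqrt(MS/df)] = c4(df) × sigma` with
`c4(df) = sqrt(2/df) Γ((df+1)/2)/Γ(df/2)`, which is 0.798 at 1 df but
0.994 at 40 df. Smoothing raw RMS values would therefore leave a
systematic ~20% gap between a technical source with *no* true effect and
the residual curve — the opposite of what the comparison is supposed to
show. `trend_curves()` consequently divides each source's RMS by
`c4(df)` before smoothing (default `bias_correct = TRUE`), making every
curve an unbiased estimate of its source's sd scale and curves of
different df directly comparable; set `bias_correct = FALSE` for raw-RMS
smoothing.

The interpretation mirrors the platform-comparison logic: if the
PrepStation upgrade adds no signal distortion, the P curve coincides with
the residual curve; the biological-sample curve should dominate everything
else; and all technical curves rise at low expression where counting noise
takes over.

## The synthetic generator

`simulate_log2()` draws the additive model the decomposition targets:
per feature `g` a uniform baseline `mu_g` on [1, 14] log2 units, sample
effects `b ~ N(0, sigma_b^2)` (one draw per sample, shared across that
feature's observations), a prep effect added when the lane's prep is
second-generation, a scanner effect likewise, per-cartridge effects, a
scan-time effect at scan 2, and independent residual noise with
expression-dependent sd `sigma_e(mu) = noise_a + noise_b · 2^(−mu/tau)` —
an exponential decay to a floor, the simplest shape with the observed
low-expression noise rise.

Defaults (all in log2 units): `sigma_b = 1` (biology dominates),
`sigma_p = 0.02`, `sigma_s = 0.1` (a prep effect at the residual level and
a slightly larger scanner effect), `sigma_c = 0.05`, `sigma_t = 0.02`
(scan-to-scan repeats are the tightest technical replicate),
`noise_a = 0.15`, `noise_b = 0.6`, `noise_tau = 2`. The noise amplitude
was calibrated so that between-cartridge lane concordance sits in the
>0.99 regime reported for this assay while the residual curve still rises
several-fold at low expression. Because the per-feature effect draws are
shared across observations, the per-feature ANOVA is the matched
estimator, and the expected mean squares have closed forms
(`truth_rms()`): e.g. under the first-scan model
`E[MS_P] = s2 + 12(sigma_p^2 + sigma_c^2)`,
`E[MS_B] = s2 + 8 sigma_b^2`, with `s2` the mean residual variance. The
cartridge terms appear in P and S because at a single scan the four
cartridges coincide with the four prep × scanner combinations; with
`sigma_c = 0` the familiar balanced-factor forms remain.

`simulate_counts()` adds the count layer: endogenous counts
`round(pmax(2^y − 1, 0) × eff_l)` with log-normal per-lane efficiency
multipliers (log2 sd 0.1), a deterministic six-step geometric
positive-control ladder scaled by the same efficiency, Poisson negatives
(mean 10), and ten stable high-expression housekeeping probes. This makes
the whole pipeline testable end to end: counts → RCC files → ingest →
normalization → log2 values that correlate >0.99 per lane with the
generating signal.

What the generator does *not* emulate: count overdispersion beyond
Poisson negatives, probe cross-hybridization, ligation-efficiency
variation, and the fact that repeated scans of a physical lane share their
hybridization chemistry (the generator draws scan noise independently, so
synthetic cross-scan concordance is close to cross-cartridge concordance
rather than markedly tighter, as it is in real data). Passing tests on
synthetic data therefore demonstrate correctness of the estimators under
the additive model, not the full error structure of real cartridges.

## Problem sizes and determinism

The test-suite and acceptance runs use the full 800-feature panel size for
the recovery and geometry checks, 5000 features for the Monte-Carlo
mean-square expectations (3-standard-error bands), and 100–400 features
for the faster structural checks. All randomness flows through a single
integer seed; the generator saves and restores the caller's RNG state, and
two runs of the pipeline with the same configuration produce byte-identical
JSON reports.

## Known limitations

* The scan2 model's `PS` term absorbs cartridge differences by
  construction (different cartridges necessarily carry the different
  instrument combinations); its interpretation is "prep+scanner *plus*
  their cartridges", which is why the C-vs-D contrast is reported
  alongside as the pure between-cartridge reference.
* Method-of-moments component recovery (`summary()` on a fit) truncates
  negative moment differences at zero and is intended for synthetic
  calibration, not as a REML replacement.
* LOESS curves are reported without confidence bands and the span is not
  cross-validated; conclusions should be read at medium-to-high
  expression, away from the trimmed boundaries.
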
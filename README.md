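# nanocompare

Concordance and variance decomposition for NanoString nCounter platform
comparisons.

## The problem

Laboratories that upgrade their nCounter System — new PrepStation, new
Digital Analyzer — need to know whether counts produced by the two
instrument generations are interchangeable before pooling datasets.
`nanocompare` implements a complete comparison framework for the standard
crossed design: six biological samples run in duplicate on four 12-lane
cartridges that cross the two PrepStation generations with the two scanner
generations (A = second/second, B = first/first, C = second prep + first
scanner, D = first prep + second scanner), each cartridge scanned twice —
96 lane-scan observations per probe.

The package provides:

* **Ingest** of vendor RCC lane files and annotated log2 matrices
  (`read_rcc()`, `read_rcc_dir()`, `read_annotated_matrix()`).
* **nCounter-style normalization** (`normalize_counts()`):
  positive-control efficiency correction (geometric-mean scaling),
  negative-control background filtering (mean + 2 sd per lane),
  housekeeping median scaling, then `log2(x + 1)`.
* **Lane concordance** (`pairwise_pcc()`, `scanpair_pcc()`): per-lane
  Pearson correlation between cartridge pairs and between repeated scans,
  plus two-way hierarchical clustering with heatmap
  (`cluster_heatmap()`).
* **Per-feature ANOVA variance decomposition** (`nano_vca()`), the core of
  the package. Three models partition each probe's variability on its 48
  relevant observations:
  * first scan: `y ~ μ + P + S + B + ε` (PrepStation, scanner, sample);
  * second scan: `y ~ μ + PS + C + B + ε` (prep+scanner sum as a 3-level
    factor, C-vs-D cartridge contrast, sample);
  * both scans of A and B: `y ~ μ + PS + T + B + ε` (A-vs-B, scan time,
    sample).

  Each term is reported as df, sum of squares, mean square and
  root-mean-square RMS = √MS.
* **LOESS RMS trend curves** (`trend_curves()`, `loess_smooth()`): each
  source's RMS smoothed against mean log2 expression on a common grid
  (tricube weights, span 0.75, degree 2), with a c4 degrees-of-freedom
  bias correction so curves from terms with different df are pointwise
  comparable.
* **A synthetic-data generator** (`simulate_log2()`, `simulate_counts()`)
  that draws the additive effects model on the full design with known
  variance components and a count-level companion (positive ladder,
  Poisson negatives, housekeeping probes, per-lane efficiencies), so the
  whole pipeline can be validated by parameter recovery.
* **A one-call pipeline** (`run_pipeline()`) and a thin CLI
  (`inst/cli/nanocompare`) with `simulate` / `normalize` / `concord` /
  `decompose` / `trend` / `run` subcommands.

## Worked example

Simulate the full study at count level, normalize, and decompose:

```r
library(nanocompare)

cfg  <- synthetic_config(seed = 42)            # 800 features, standard design
sim  <- simulate_counts(cfg)
norm <- normalize_counts(lanes_to_matrix(sim$lanes), norm_config())
endo <- norm[norm$features$code_class == "Endogenous", ]
endo
#> ncounter_matrix: 598 features x 96 lanes (scale: log2 )
#>   probe classes: Endogenous=598
#>   cartridges: A, B, C, D | scans: 1, 2
```

598 of the 800 simulated features survive background filtering (the rest
sit at negative-control noise level by construction). Lane concordance
between the all-second-generation cartridge A and the all-first-generation
cartridge B at the first scan:

```r
pcc_range(pairwise_pcc(endo, c("A", "B"), scan = 1))
#>       min       max
#> 0.9939236 0.9953887
```

All 12 matched lane pairs correlate above 0.99: the two generations
produce equivalent signals at lane level. The variance decomposition says
where the remaining variability lives:

```r
fit <- nano_vca(endo, "scan1")
summary(fit)
#> Variance decomposition summary (model: scan1 , 598 features)
#>
#> Mean squares by source:
#>        P        S        B residual
#>  0.08429  0.19418  8.13730  0.04791
#>
#> Method-of-moments effect-sd estimates (log2 units):
#> sigma_b sigma_p sigma_s
#>  1.0056  0.0551  0.1104
```

The biological-sample mean square dwarfs every technical source, and the
moment estimates recover the generating standard deviations
(`sigma_b = 1`, `sigma_p = 0.02`, `sigma_s = 0.1`) up to sampling error —
the prep estimate 0.055 reflects that a 0.02 effect is below this design's
resolution, exactly the "no PrepStation difference" regime.
`plot(fit)` draws the LOESS RMS trend curves (biology on top, technical
sources hugging the residual curve at medium-high expression and rising at
low expression); `run_pipeline(run_config(mode = "synthetic"))` writes the
full artifact set — PCC tables, heatmap, per-model ANOVA tables, curve
TSV/PNGs and a JSON report.

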
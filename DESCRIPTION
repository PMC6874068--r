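Package: nanocompare
Title: Concordance and Variance Decomposition for NanoString nCounter
    Platform Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing generations of the NanoString nCounter
    System on a common set of biological samples. Reads RCC lane files and
    annotated log2 expression matrices, performs nCounter-style
    normalization (positive-control efficiency correction, negative-control
    background filtering, housekeeping median scaling), computes per-lane
    Pearson concordance between cartridges and repeated scans, fits
    per-feature ANOVA models that partition variability into prep-station,
    scanner, cartridge, scan-time, biological-sample and residual sources,
    and smooths the per-source root-mean-square against mean expression
    with LOESS trend curves. Includes a synthetic-data generator for the
    4-cartridge by 2-scan duplicate design with known variance components
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
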
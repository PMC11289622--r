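Package: peritract
Title: Peri-Tract Spatial Gene Expression and Recording-Quality Analysis for
    Implanted Cortical Microelectrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking spot-based spatial transcriptomics
    around an implanted cortical microelectrode tract to extracellular
    recording quality. Provides annular (100 micrometre) binning of
    expression spots by centroid distance from the device tract,
    median-normalized average (MNA) depth normalization, negative-binomial
    exact-test differential expression with low-count and significance
    filters, the full SNR / multi-unit activity / local field potential
    signal-quality algorithm (common average reference, 500-6000 Hz spike
    band, threshold snippet extraction, noise-floor channel inclusion),
    radial immunohistochemistry quantification, and a log-fold-change versus
    R-squared regression / principal-component-regression screen that
    nominates candidate biomarker genes. A seeded synthetic-data module
    generates Visium-like spot lattices, spike-plus-noise recordings, and
    multi-sample cohorts with known ground truth so that every stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
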
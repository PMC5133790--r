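Package: pepscreen
Title: Urinary Peptidome Biomarker Screening with Sparse PLS-DA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end discovery pipeline for capillary-electrophoresis
    mass-spectrometry (CE-MS) urinary peptidomics. Reads per-sample peptide
    peak lists (mass, normalized migration time, normalized intensity),
    compiles them into a master abundance matrix using ppm mass and
    migration-time tolerances, fits sparse partial least squares-discriminant
    analysis (sPLS-DA) models from scratch, searches a grid of model
    complexities by rat-level 10-fold cross-validation, screens candidate
    biomarkers by a multi-model loading consensus plus a detection-frequency
    filter, and reports per-group abundances with signed ratio fold changes.
    A zero-inflated log-normal simulator generates datasets with planted
    discriminant peptides so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
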
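Package: normqc
Title: Normative-Modelling Quality Control for Imaging-Derived Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control of tabular imaging-derived phenotypes (IDPs)
    by normative modelling. Fits per-phenotype warped Bayesian linear
    regression models over age (cubic B-spline basis, sinh-arcsinh
    likelihood warping), derives per-subject deviation z-scores and
    centile curves, flags extreme outliers, and compares the approach
    against visual and quantitative QC via inter-rater reliability
    (ICC3k), class-balanced cross-validated linear SVM evaluation, and
    precision-recall threshold sweeps. Includes a synthetic cohort
    generator with age-dependent non-Gaussian phenotypes, rare multi-class
    artefact contamination, simulated raters and quality descriptors, so
    the full pipeline is exercisable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
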
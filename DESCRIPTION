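Package: protrisk
Title: Proteomic Recurrence-Risk Modelling for Pediatric Papillary Thyroid Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of a proteomic prognostic
    workflow for pediatric papillary thyroid carcinoma (PPTC): quality control
    and preprocessing of TMT protein abundance matrices (coefficient-of-variation
    reporting, missingness filtering, robust sequential imputation,
    empirical-Bayes batch correction, replicate merging), Welch/Benjamini-Hochberg
    differential expression, clinical Cox proportional-hazards survival analysis,
    stability-selected random-survival-forest recurrence models with LASSO-Cox
    and grid-search tuning, and restricted-mean-survival ("Crank") based
    high/low recurrence-risk stratification. A synthetic cohort generator with
    planted ground truth (differential proteins, prognostic signal proteins,
    batch effects, abundance-dependent missingness, heavy censoring) makes every
    stage testable without access to the original patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocParallel,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    survival,
    sva,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
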
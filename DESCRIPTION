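Package: glucodyn
Title: Personalized Glucose-Insulin Modeling from OGTT and CGM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiology-based modeling of insulin-regulated glucose metabolism
    for personalized analysis of oral glucose tolerance tests (OGTT). Implements
    a compartmental glucose-insulin ODE model extended with an interstitial
    glucose compartment so that continuous glucose monitoring (CGM) traces can
    be used in place of plasma glucose during calibration. Provides per-subject
    parameter estimation by Sobol-seeded multistart bounded optimization,
    practical-identifiability analysis via profile likelihood with observable
    confidence bands, fasting- and OGTT-derived metabolic indicators (HOMA,
    Matsuda, insulinogenic index, MISI, HIRI, disposition index), a synthetic
    cohort generator with configurable sensor noise, missingness and exclusion
    rules, and a cohort-scale pipeline comparing plasma-calibrated against
    CGM-calibrated models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
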
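Package: wqsmix
Title: Two-Index Weighted Quantile Sum Regression for Essential and Toxic Metal Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying joint effects of prenatal urinary metal
    mixtures on child neurodevelopment. Implements decile coding of
    creatinine-adjusted exposures, Spearman correlation screening,
    penalized-spline (GAM) and restricted-cubic-spline detection of
    non-linear exposure-response shapes, and a two-index Weighted Quantile
    Sum (WQS) regression that trains non-negative simplex weights for an
    essential-metal index and a toxic-metal index by penalized bootstrap,
    validates both indices jointly with optional quadratic terms, selects
    index directions by AIC, and summarises estimates over repeated random
    training/validation holdouts. A calibrated synthetic cohort generator
    (Gaussian-copula log-normal exposures with limit-of-detection
    censoring, realistic covariates, and outcomes from a known two-index
    process) makes every stage testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
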
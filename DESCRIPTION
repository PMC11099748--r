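Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: allele harmonization, instrument selection with
    LD clumping and strength diagnostics, univariable estimators (IVW,
    MR-Egger, weighted median, maximum likelihood) with heterogeneity and
    pleiotropy diagnostics (Cochran's Q, Egger intercept, MR-PRESSO,
    radial MR, Steiger directionality), multivariable MR (IVW, Egger,
    median, Lasso), and two-step MR mediation analysis with delta-method
    standard errors for mediating effects and mediated proportions. A
    synthetic summary-statistic generator with a known causal chain
    (exposure, mediator, outcome) supports calibration and validation at
    desk scale.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
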
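Package: neovanc
Title: Population Pharmacokinetics of Vancomycin in Neonates and Young
    Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic (PopPK)
    modelling of intravenous vancomycin in neonates and young infants.
    Provides closed-form two-compartment infusion kinetics, a
    first-order-conditional (FOCE) estimation engine with empirical Bayes
    estimates, shrinkage and conditional weighted residuals, stepwise
    covariate selection on objective-function-value thresholds,
    non-parametric bootstrap and visual predictive checks, external
    validation metrics (MPE/MAE/MSPE), individual trough prediction for
    therapeutic drug monitoring, and a synthetic-cohort generator that
    emulates sparse neonatal TDM data. All tabular inputs and outputs are
    data frames / tibbles designed for pipe-based workflows.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
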
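Package: netmr
Title: Network Mendelian Randomization with Two Genetic Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of total, direct and indirect causal effects of an
    exposure on an outcome through a candidate mediator, using separate
    genetic instrumental variables for the exposure and the mediator.
    Implements the ratio (Wald) and two-stage least squares estimators,
    a regression-based mediation decomposition with bootstrap standard
    errors, a multiple-stage least squares estimator, Gaussian maximum
    likelihood estimation of the five-variable linear path model with
    correlated errors (with delta-method standard errors for the indirect
    effect), reciprocal Mendelian randomization for orienting the causal
    direction between exposure and mediator, and a Monte Carlo simulation
    engine for studying the estimators under individual-level effect
    heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
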
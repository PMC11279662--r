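Package: salbupop
Title: Population Pharmacokinetics of Inhaled Salbutamol from Virtual Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual patient cohorts and concentration-time data for
    inhaled salbutamol from a two-compartment first-order-absorption population
    model, and fits the nonlinear mixed-effects model by stochastic-approximation
    EM (SAEM). Includes noncompartmental analysis (linear trapezoidal AUC,
    adjusted-R-squared terminal-slope selection), stepwise covariate selection
    with ANOVA/Pearson screening and Wald confirmation, and model-evaluation
    surfaces: weighted residuals, normalized prediction distribution errors,
    visual predictive checks, and corrected information criteria.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
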
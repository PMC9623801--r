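Package: calfgrowth
Title: Bayesian Variance Partition of Dairy-Calf Weight from Birth to Twenty Weeks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling longitudinal weight recordings of dairy calves
    nested within farms and veterinary practices. Provides a synthetic-data
    generator that emulates national calf weight-recording databases (irregular
    weighing schedules, attrition with age, and the data-entry defects a
    selection pipeline must remove), an ordered record-selection cascade with
    per-stage inclusion reporting, a Gibbs sampler for the three-level
    random-slope linear mixed model with conjugate Gamma and Wishart priors,
    chain diagnostics (effective sample size, Raftery-Lewis run lengths, DIC),
    and derived quantities: age-dependent variance partition coefficients,
    instantaneous and cumulative growth rates, cluster-specific quantile
    coverage, and posterior predictive weight distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
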
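Package: fdstm
Title: Functional Dynamic Spatio-Temporal Modelling of Hourly Pollutant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical state-space modelling of hourly air-quality
    monitoring panels in which daily pollutant profiles are treated as
    functional data on a period-24 Fourier basis. Covariate effects and the
    measurement-error variance are smooth periodic functions of hour-of-day,
    and a latent spatially correlated process with diagonal first-order
    Markov dynamics carries the spatio-temporal dependence. Provides exact
    Kalman filtering and smoothing with missing data, maximum-likelihood
    estimation by an expectation-maximisation algorithm, standard errors from
    the marginal likelihood, Wald chi-square tests and pointwise confidence
    bands for functional covariate effects, forward covariate selection and
    basis-size grids under an information criterion, held-out-station kriging
    prediction, two-fold and leave-one-station-out cross-validation, and a
    generative simulator for study-like synthetic panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
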
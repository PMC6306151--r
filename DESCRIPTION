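Package: bitecast
Title: Interrupted Time-Series Evaluation of Injury Count Interventions
Version: 0.1.0
Authors@R: person("Accident Analytics", "Maintainers", email = "maint@example.org", role = c("aut", "cre"))
Description: Tools for evaluating policy interventions on hospital-treated
    injury count series aggregated to half-year periods. Implements a naive
    before/after Poisson contrast (rates, rate differences and rate ratios
    with Wald confidence intervals), pre-period ARIMA model selection by
    one-step root mean squared prediction error, out-of-sample counterfactual
    forecasting on the log scale, and Monte Carlo effect estimation that
    combines a log-normal predictive distribution for the counterfactual with
    Poisson sampling noise around the observed counts. Includes a synthetic
    data generator (latent log-scale trend plus ARMA noise, Poisson
    observation, configurable step or ramp intervention effects), a Poisson
    pre/post power calculator, plotting, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
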
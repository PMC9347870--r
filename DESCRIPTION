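Package: epigrowth
Title: Reproduction Numbers and Epidemic Growth Rates from Incidence Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A unified toolkit for estimating and inter-converting the
    instantaneous reproduction number (Rt) and the instantaneous epidemic
    growth rate (rt) from daily case incidence. Implements renewal-model
    simulation of epidemics under arbitrary time-varying transmissibility,
    Bayesian grid filtering and smoothing of Rt with equal-tailed credible
    intervals and one-step-ahead predictive validation, Savitzky-Golay
    derivative filters for model-agnostic growth-rate estimation (including
    the total infectiousness viewed as an implicit epidemiological smoothing
    kernel, with lag alignment), and moment-generating-function transforms
    between Rt and rt (gamma closed form, numeric root, and linearised SIR).
    Ships end-to-end seasonal-epidemic and generation-time-misspecification
    experiments with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
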
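Package: ifngate
Title: Delayed Negative Feedback and Cell-Cycle Gating in Interferon Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinetic modelling of interferon-stimulated gene induction with a
    fast IRF9-mediated positive feedback loop and a delayed, cell-cycle-gated
    USP18-mediated negative feedback loop.  Provides forward-Euler integration
    of the production-only two-species model under arbitrary piecewise-constant
    interferon input programs, stochastic single-cell cohort simulation with
    additive expression noise, least-squares parameter estimation with a delay
    scan and AIC-based comparison of loop-ablated model variants, the analytic
    cell-cycle gating delay distribution with window-length fitting, synthetic
    dual-reporter single-cell trace generation, and quantification of reporter
    traces (activation times, delay times, cell-cycle progression, induction
    amounts).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
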
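Package: pflswitch
Title: Bistable Switch Analysis of the Twist1-Prrx1-TNC Positive Feedback Loop
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of the Twist1-Prrx1-TNC
    positive feedback loop that governs fibroblast activation, together with
    the systems-level analyses the model supports: fixed-point and stability
    analysis, quasi-static stimulus sweeps, hysteresis thresholds and the
    delta-TNC irreversibility measure, reversible/irreversible phase diagrams,
    exogenous-TNC injection protocols, induction-delay kinetics,
    maximum-likelihood parameter estimation by a genetic algorithm with local
    refinement, and synthetic western-blot-like time-course, dose-response and
    single-cell datasets for validating the estimation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
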
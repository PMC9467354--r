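Package: reachadapt
Title: Models of Motor Adaptation to Velocity-Dependent Force Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of planar arm reaching movements under
    velocity-dependent (curl) force fields. Implements three models of motor
    adaptation: a compensation model (desired minimum-jerk trajectory, inverse
    dynamics and an adapted compensatory torque), a reoptimization model
    (receding-horizon optimal feedback control of a two-link arm with a
    second-order muscle model, via-point goal scheduling, iterative LQR and a
    delay-aware Kalman state estimator), and a redirection model (the same
    controller aiming at spatially remapped via-points). Includes the
    trajectory-angle analysis pipeline (zero-phase Butterworth filtering,
    numerical differentiation, movement extraction, lateral deviation, peak
    frequency, exponential adaptation fits), per-timestep t-tests and JZS Bayes
    factors for the mirror after-effect prediction, and a seeded synthetic
    participant generator for end-to-end testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
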
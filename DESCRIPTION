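Package: vfadesign
Title: Optimal Flip Angle Design and Kinetic Model Fitting for
    Hyperpolarized Magnetic Resonance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing excitation schedules and estimating kinetic
    parameters in dynamic hyperpolarized magnetic resonance experiments with a
    two-metabolite unidirectional conversion model. Provides the discrete-time
    forward model (relaxation, conversion, flip-angle excitation losses),
    analytic signal sensitivities, Fisher information and Cramer-Rao bounds,
    L-optimal design of constant and variable flip-angle schemes robust to B1
    transmit-field miscalibration through a prior-marginalized objective,
    bounded maximum-likelihood fitting of the kinetic model with or without a
    B1 scale parameter, and Monte Carlo harnesses for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
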
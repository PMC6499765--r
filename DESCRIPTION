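Package: radtse
Type: Package
Title: Long-Term Tumor Growth, Kill and Tumor Static Exposure for
    Radiation-Radiosensitizer Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and population analysis of fractionated radiotherapy
    combined with a radiosensitizing agent in xenograft studies. Implements a
    six-compartment impulsive-dose tumor model with linear-quadratic (LQ) cell
    kill, permanent radiation-induced growth inhibition driven by accumulated
    effective dose, and one-compartment radiosensitizer pharmacokinetics.
    Provides Tumor Static Exposure (TSE) analytics (static-exposure curves,
    isoclines, net-growth-rate heat maps, population TSE fans, allometric
    scaling invariance), a Laplace/FOCE-class nonlinear mixed-effects
    estimator for longitudinal tumor-volume data, and generators for complete
    in-silico xenograft and sparse-sampling PK studies with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
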
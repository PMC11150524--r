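Package: ferroflow
Title: Ferrohydrodynamic Channel Flow Simulation and Boosted Surrogate
    Models of Blood Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage hybrid model of blood flow through a vessel segment
    carrying magnetic drug nanocarriers. A finite-volume solver for the 2D
    incompressible Navier-Stokes equations with a Kelvin magnetic body force
    generates a velocity dataset (x, y, U) on a plane channel with a pulsatile
    parabolic inlet; an AdaBoost.R2 ensemble over decision-tree, k-nearest
    neighbour and multilayer-perceptron base regressors learns a fast surrogate
    of the velocity field. Includes isolation-forest outlier screening,
    min-max normalisation, a bat-algorithm hyperparameter tuner, and
    diagnostics (R2/RMSE reports, staged-estimator curves, learning curves,
    partial dependence, prediction surfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    rpart,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
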
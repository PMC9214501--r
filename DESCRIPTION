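Package: ddcr
Title: Dynamical Differential Covariance for Directed Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates directed functional connectivity from multivariate
    neural time series with dynamical differential covariance (DDC), a family
    of estimators obtained as the least-squares solution of an assumed
    dynamical system: the coupling matrix W is approximated by the
    time-averaged outer product of the signal derivative with the signal,
    multiplied by the inverse of the (possibly nonlinearly transformed) state
    covariance.  Includes the covariance, precision, regularized precision,
    differential-covariance and spike-train cross-correlogram baselines;
    multiscale ground-truth simulators (linear and sigmoid stochastic
    networks, the Rossler system, a two-state nonstationary process, sparse
    leaky integrate-and-fire networks, and a reduced Wong-Wang mean-field
    model); an analytic Lyapunov steady-state covariance solver; evaluation
    statistics (error bias/variance decomposition, ROC/AUC, c-sensitivity,
    subject identification); and an autoregressive-bootstrap significance
    test for estimated connections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    igraph,
    deSolve,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
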
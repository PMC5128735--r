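Package: gatefit
Title: Fitting Continuous-Time Markov Models of Ion Channel Gating to
    Voltage-Clamp Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating, and fitting continuous-time
    Markov models of ion channel gating. Voltage-clamp protocols are
    decomposed into piecewise-constant voltage steps so that state
    occupancies can be propagated with the matrix exponential instead of
    general-purpose ODE integration. Transition rates are generated from
    independent per-state and per-edge parameters so that microscopic
    reversibility (detailed balance) holds at every voltage by
    construction. Model structure and rate parameters are optimized
    jointly with synchronous multi-chain simulated annealing, with an
    eigenvalue-based stiffness penalty that steers the search away from
    numerically stiff models. Ships protocol definitions for cardiac
    sodium (Nav1.5-style) and KCNQ1-style potassium channels and a
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
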
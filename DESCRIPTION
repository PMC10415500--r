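Package: turingfit
Title: Predicting Reaction-Diffusion Parameters from Single Turing Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the inverse problem of Turing pattern formation:
    simulate Gierer-Meinhardt reaction-diffusion patterns on doubly periodic
    grids with an implicit-Euler/FFT scheme, represent each steady-state
    pattern invariantly by histograms of effective (resistance) distances on
    its weighted pattern graph, and learn pattern-to-parameter maps with
    Wasserstein-kernel support vector regression, operator-valued-kernel
    joint regression, and small feedforward networks. Includes linear
    stability analysis (dispersion relations and the Turing instability
    test), Wasserstein/chi-squared histogram kernels, the full data
    splitting and averaged-NRMSE evaluation protocol, and Wasserstein
    neighborhood-graph clustering of pattern collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    boot,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
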
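Package: connscape
Title: Simulation-Based Evaluation of Landscape Connectivity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating resistance-based landscape connectivity
    models against a simulated "known truth". Provides a generator of
    synthetic resistance surfaces of graded spatial complexity, an
    individual-based stochastic movement simulator (biased random walks
    driven by energy, attraction to low resistance, mortality risk,
    directional autocorrelation and destination bias, with multi-scale
    perception), three connectivity predictors (factorial least-cost
    paths, resistant kernels, circuit-theory current density), map
    accuracy statistics (RMSE, Pearson correlation, top-decile spatial
    overlap), and multivariate synthesis of factorial experiments via
    redundancy analysis, canonical correspondence analysis, variance
    partitioning and factorial ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
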
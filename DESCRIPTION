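Package: cetempo
Title: Covariant Evolutionary Tempo Birth-Death Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Numerical tools for a birth-death model of diversification in
    which speciation, extinction and molecular rates are all scaled by a
    single diffusing "tempo" variable whose log follows a self-scaled
    Ornstein-Uhlenbeck process. Provides finite-difference solvers for the
    probability generating function of clade size, its FFT inversion to
    clade-size distributions and sister-group imbalance, moment equations
    for expected species and lineage numbers, the replicator-mutation
    equation for the tempo distribution and its equilibrium, posterior
    distributions of historical tempo, branch duration and molecular
    branch-length densities, and an exact-event Monte Carlo simulator that
    generates annotated Newick trees and serves as an independent check on
    every deterministic solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
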
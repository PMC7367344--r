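Package: gelkin
Title: Nonequilibrium Kinetics of Colloidal Gelation with Short-Range Attraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study gelation of short-range attractive colloids as a
    nonequilibrium percolation transition. Provides Mie and continuous
    square-well pair potentials with second virial coefficients and the Baxter
    adhesive-hard-sphere stickiness mapping; a Langevin dynamics simulator for
    binary particle mixtures in periodic boxes; cluster and percolation order
    parameters (coordination number, largest-cluster fraction, correlation
    length, cluster-mass distributions, fractal dimension); association and
    dissociation rate constants extracted from finely sampled trajectories; an
    analytically solvable coagulation-fragmentation master equation with
    single-particle chipping, its generating-function steady state, critical
    point and power-law cluster-mass tails; and critical-scaling fits for the
    divergences that mark the sol-gel transition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
SystemRequirements: FFTW3
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
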
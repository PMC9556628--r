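Package: mitoscaling
Title: Finite-Size Scaling Analysis of Mitochondrial Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic models of mitochondrial fission-fusion dynamics and the
    finite-size scaling machinery needed to place them in a percolation
    universality class. Provides an agent-based (mean-field) fission-fusion
    simulator, a spatially-explicit anisotropic bond model on a 2D lattice,
    percolation observables (order parameter, second-largest cluster, mean
    cluster size, susceptibility), pseudo-critical point location,
    critical-exponent estimation from cluster-size distributions with one or
    two cutoffs, universality-class assignment, a pixel-mass cluster pipeline
    for fluorescence mask images, and synthetic-data generators (power-law
    censuses with exponential cutoffs, critical random graphs, rendered mask
    images) used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    tools,
    utils,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
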
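Package: edgedrop
Title: SIR Epidemics on Configuration-Model Networks with Preventive Edge Dropping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Markovian SIR epidemic on configuration-model
    networks in which susceptible individuals drop edges to infectious
    neighbours at a constant per-edge rate. Provides exact stochastic
    simulation via the effective-degree Markov chain and an explicit-graph
    backend, the deterministic (law-of-large-numbers) limit in real and
    transformed time with closed-form solutions, Gaussian fluctuation
    (central-limit) machinery including the covariance ODE and hitting-time
    projection, near-explicit asymptotic variances of the final size on
    Molloy-Reed and Newman-Strogatz-Watts graphs, branching-process
    approximations of the early epidemic, and specializations to the classical
    network SIR model and the configuration-model giant component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
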
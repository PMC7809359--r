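Package: neuroprune
Title: Dendritic Pruning and Excitable Dynamics on Neuronal Morphologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates age-related dendritic pruning on compartmental
    neuronal morphologies and its dynamical consequences. Parses SWC
    reconstructions into single-soma compartment trees, iteratively removes
    terminal dendritic compartments, and runs a stochastic excitable
    cellular automaton (susceptible/active/refractory with propagation
    probability P and external drive rate h) on each pruned stage. Derived
    measures include compartmental firing rates, soma response functions and
    dynamic range, total and relative energy consumption, soma centrality,
    and a branch-centrality functional classification. Synthetic morphology
    generators (chains, stars, Cayley trees, random trees) and closed-form
    rate oracles make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
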
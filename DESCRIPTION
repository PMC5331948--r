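Package: httnet
Title: Simulation and Analysis of Horizontal Transposon Transfer Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how ecological network structure shapes the
    horizontal transfer of transposable elements (TEs) between species
    genomes. Generates ecological networks of contrasting topologies
    (complete, random, scale-free, modular, bipartite), simulates the
    stochastic flow of TE families over a network (intragenomic
    transposition plus horizontal transposon transfer, HTT), reduces
    simulations to presence/absence and Jaccard beta-diversity matrices,
    quantifies how robustly the beta-matrix fingerprints the underlying
    network (Mantel correlation under edge-shuffle perturbation,
    single-family propagation dynamics), and reconstructs candidate
    networks from a beta-matrix by similarity thresholding,
    mutual-information scoring, and simulation-based (ABC-style)
    candidate ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
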
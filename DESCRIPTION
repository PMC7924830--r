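Package: cladewave
Title: Lattice Simulation and Approximate Bayesian Inference of
    Intra-Species Clade Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of successive
    mitochondrial-clade range expansions on a habitable lattice, with
    gamma-kernel dispersal and probabilistic replacement on contact
    between clades. Summarises observed or simulated site tables with
    nested-clade phylogeographic distances (Dc, Dn) and Mantel spatial
    autocorrelation, and estimates migration timing, dispersal rate and
    scale, and the clade replacement rate by rejection approximate
    Bayesian computation, including a test of the neutral replacement
    value 0.5. Ships synthetic landscape, dataset and alignment
    generators plus small sequence utilities (haplotype deduplication,
    p-distances, between-group distances, evolutionary-rate conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
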
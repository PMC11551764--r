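Package: neurotopo
Title: Higher-Order Topology of Cortical Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of the higher-order (simplicial) structure of directed
    synaptic connectomes. Enumerates directed flag-complex simplices in the
    excitatory subnetwork, quantifies divergent feed-forward information flow,
    positions inhibitory neurons relative to simplex motifs, measures
    disynaptic inhibition between simplices and its symmetry, tests for
    disinhibitory targeting with a hypergeometric null, clusters simplices
    into source and target groups by neuron overlap, scores the complexity of
    node neighborhoods against degree-preserving controls, and simulates a
    plasticity-inspired rewiring rule. Includes distance-dependent,
    configuration-model and Erdos-Renyi null models, and a synthetic-data
    generator producing connectomes and activity traces with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    arrow,
    mclust,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
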
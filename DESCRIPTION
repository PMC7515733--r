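Package: transitr
Title: Transition Cells, Intermediate States and Transition Genes from
    Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised quantification of transition cells and intermediate
    cell states from single-cell expression matrices. Builds a consensus
    cell-cell similarity matrix from repeated clusterings, soft-clusters it by
    symmetric nonnegative matrix factorization, scores each cell's plasticity
    with an entropy-based index, embeds cells by probabilistic regularized
    embedding, and infers transition trajectories, pseudotime, cluster marker
    genes and transition genes. Ships two generative models used as ground
    truth: a multiscale agent-based simulator of an 18-species
    epithelial-mesenchymal transition gene regulatory circuit with stochastic
    division, and a population-level model of transitions through intermediate
    states with adaptation, noise-attenuation and transition-efficiency
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    Matrix,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
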
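Package: emtnet
Title: Multiscale Analysis of Epithelial-Mesenchymal Transition from
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the multiscale regulatory architecture of
    epithelial-mesenchymal transition (EMT) from single-cell RNA-seq
    expression matrices. Provides consensus-similarity soft clustering via
    symmetric non-negative matrix factorization with eigen-gap selection of
    the number of cell states, an entropy-based cell plasticity index and
    transition-cell identification, trajectory and pseudotime inference,
    ligand-receptor cell-cell signaling probabilities aggregated to a
    directed cluster-cluster communication network, gene regulatory network
    inference per cell state via partial information decomposition, and
    assembly of a hierarchical multilayer network with strength, closeness
    and PageRank centralities. Ships a synthetic single-cell data generator
    with planted clusters, transition cells, trajectory, time-point
    synchrony and sender-receiver signaling for end-to-end validation.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Matrix,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
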
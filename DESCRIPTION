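Package: hoinfo
Title: Higher-Order Information Analysis of Neuronal Parameter Ensembles and
    Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies higher-order statistical interactions (synergy and
    redundancy) in sample-by-variable ensembles such as conductance-based
    neuron model parameters and single-cell ion-channel gene expression.
    Implements closed-form Gaussian information measures (entropy, mutual
    information, total correlation, dual total correlation, O-information,
    and the redundancy-synergy index), tuple scans across interaction orders
    with top-fraction frequency maps, minimal synergistic set extraction and
    stabilization-point detection, bootstrap and column-shuffle surrogate
    inference with trajectory AUC summaries, PCA-residual selection of
    high-covariance sub-ensembles, histogram mutual-information maps with
    permutation significance and FDR control, gene-panel clustering with a
    random-panel adjusted-Rand-index null, and seeded synthetic generators
    for constraint-conditioned, latent-factor, cluster-mixture, feature-map,
    and zero-inflated count ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    mclust,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
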
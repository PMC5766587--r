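Package: acanet
Title: Anti-Correlated Network Analysis of Multielectrode Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spontaneous multielectrode-array spike
    recordings as count processes across logarithmically spaced timescales.
    Provides spike-train I/O and firing statistics (interspike intervals,
    low-rate filtering, Taylor fluctuation-scaling fits, spike-width
    classification), permutation-thresholded functional-connectivity graphs
    with degree and assortativity measures, anti-correlated component
    analysis (ACA) -- a constrained bilinear minimisation that splits a
    neuronal population into two mutually exclusive, maximally
    anti-correlated networks -- and entropy/Cohen's-kappa quantification of
    how those networks blend across timescales. A doubly stochastic
    (Cox-process) spike simulator with anti-correlated Ornstein-Uhlenbeck
    latent drives supports calibration and end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils,
    graphics,
    rlang,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
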
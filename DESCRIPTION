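Package: copong
Title: Cross-Species Co-Module Discovery and Expression Conservation
    Statistics via the Ping-Pong Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies co-modules -- coherently over-expressed sets of
    genes from two species together with the homologous organ groups in
    which they are expressed -- by alternating thresholded projections
    between two expression matrices sharing one dimension (the Ping-Pong
    Algorithm). Provides the co-module post-processing cascade
    (score-correlation redundancy elimination, minimum-size filtering,
    fully-overlapping-set reduction), the expression-conservation rate
    gamma with an orthology-preserving permutation null and a
    replicate-split ceiling, gene-set enrichment statistics
    (hypergeometric overlap, Fisher term enrichment, Wilcoxon dN/dS shift,
    Bonferroni correction), and a paired-species synthetic data generator
    with planted, partially conserved co-modules for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
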
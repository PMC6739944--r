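Package: epimotif
Title: Multi-Task Convolutional Sequence Models for Histone-Mark
    Prediction and Motif Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and interprets paired multi-task convolutional neural
    networks that predict histone-modification status of genomic bins from
    DNA sequence alone: a cell model (tasks are the marks measured in one
    cell type) and a mark model (tasks are the cell types for one mark).
    Provides ChIP-seq peak filtering and replicate consolidation, genome
    binning and one-hot encoding, a CPU CNN trainer with RMSprop and early
    stopping, first-layer filter-to-PWM extraction, nullification-based
    influence scores, pairwise motif interaction coefficients, motif
    comparison and bidirectional-best-hit merging, FIMO-style PWM scanning
    against a Markov background with conservation analysis, a seeded
    synthetic planted-motif epigenome generator, and a command-line
    interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    ape,
    Biostrings,
    IRanges
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
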
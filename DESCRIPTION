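Package: peakgl
Title: Discriminative Wildcard k-mer Group Lasso for Regulatory Sequence
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns transcription-factor sequence signals de novo from
    ChIP-seq, DNase-seq or ATAC-seq peak calls by training a sparse group
    lasso logistic regression that discriminates peak windows from flanking
    background windows using wildcard k-mer count features.  Selected
    k-mers are clustered into co-occurrence groups that act as the group
    lasso blocks; fitted groups are associated with a class, peaks
    significantly explained by each group are called against an empirical
    null at a controlled false discovery rate, and per-peak binding hits
    are localized and exported as motif-ready windows.  A multitask
    variant separates sequence signals shared between two peak sets from
    context-specific ones.  Includes a synthetic sequence generator with
    planted motif instances and a ground-truth table for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    jsonlite,
    methods,
    stats,
    stringi,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
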
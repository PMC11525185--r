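Package: credesign
Title: Model-Guided Design of Cell-Type-Specific Cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A platform for designing short (200 nt) cis-regulatory elements
    with programmed cell-type specificity. Provides a convolutional
    sequence-to-activity model trained on massively parallel reporter assay
    (MPRA) log2 fold-change tables, three sequence-design algorithms
    (gradient-based Fast SeqProp, evolutionary AdaLead, and simulated
    annealing) driven by a MinGap/bent-MinGap specificity objective with
    optional motif penalization, and an interpretation stack: sampled
    integrated gradients attribution, contribution-block ablation,
    contribution-score motif scanning, motif-program decomposition by
    non-negative matrix factorization, and propeller specificity geometry.
    A synthetic-MPRA generator with a planted activator/repressor motif
    grammar makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
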
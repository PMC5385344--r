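Package: nbmine
Title: Nanobody Discovery from Phage-Display Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines candidate antigen-binding nanobodies (VHH domains) from
    paired-end amplicon sequencing of phage-display selection outputs. Merges
    read pairs by overlap, applies Phred and length filters, orients reads on
    the framework-1/framework-4 PCR primers, translates and removes frameshifted
    or stop-containing reads, clusters trimmed peptides with a greedy
    incremental algorithm at a calibrated sequence-identity threshold, computes
    cross-sample enrichment factors with depth normalization and a pseudocount,
    selects candidate binders, and emits majority-rule consensus peptides with
    synthesis-ready reverse-translated DNA. Includes a threshold-calibration
    procedure against labeled reference nanobody sets and a ground-truth
    repertoire simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    igraph,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
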
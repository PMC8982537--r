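Package: enhloops
Title: Identification of Enhancer-Mediated Feed-Forward and Feedback
    Regulatory Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives tissue-specific regulatory edges among transcription
    factors, enhancers, microRNAs and protein-coding genes from enhancer
    intervals, ChIP-seq binding peaks, transcription start site annotations
    and multi-source miRNA-target evidence.  Integrates miRNA-target support
    into a confidence score, tests transcription factor and enhancer
    co-regulation with a hypergeometric joint-target test under
    Benjamini-Hochberg false discovery rate control, and assembles four
    classes of enhancer-mediated feed-forward and feedback loops.  A seeded
    synthetic-landscape generator with a truth ledger of planted loops
    supports end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    IRanges,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
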
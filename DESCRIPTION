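Package: regrescue
Title: Genetic-Rescue Regulatory Analysis of Transcription-Factor Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genetic-rescue assays in which a wild-type
    transcription factor and a pathogenic variant are re-expressed in
    enhancer-mutant progenitor cells. Provides a negative-binomial Wald
    differential-expression engine with Benjamini-Hochberg correction,
    classification of genes into rescue/ectopic regulatory categories across
    three contrasts, differential chromatin-accessibility integration with
    nearest-gene peak linking and promoter-window analysis, IUPAC consensus
    motif scanning including composite E-box-spacer-WGATAR and tandem
    double-WGATAR grammars, occupancy peak-set comparison, and a fully
    self-contained synthetic-data generator with ground-truth labels so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
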
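Package: cfties
Title: Plasma Epigenomic Scoring of Fusion-Driven Renal Cancer from Cell-Free ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tumor-subtype epigenomic signatures from cell-line ChIP-seq
    peak data and quantifies them in plasma cell-free ChIP-seq fragments to
    compute an integrated epigenomic score for translocation renal cell
    carcinoma (tRCC). Provides a genomic-interval engine with BED input and
    output, differential peak selection over per-peak count matrices, aggregate
    profile quantification with shoulder and housekeeping-site normalization,
    ROC/AUC and Youden-threshold classification with leave-one-out
    cross-validation, an in silico dilution experiment for limit-of-detection
    estimation, longitudinal monitoring statistics, and a synthetic cohort
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    yaml,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
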
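Package: ifnmodmap
Title: Differential-Expression Filtering, Gene-List Concordance and
    Promoter-Module Enrichment for Interferon Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible inference chain from MAS5-style microarray
    signal/detection-call tables to a cis-regulatory conclusion:
    rule-based differential-expression filtering (detection calls,
    intensity floor, Welch's t-test, fold-change thresholds),
    cross-condition directional concordance of gene lists,
    position-weight-matrix scanning and two-motif promoter "framework"
    matching with an appearance-ratio enrichment statistic, and the
    delta-delta-Ct / time-course arithmetic used for qPCR validation.
    Includes a synthetic-data generator with planted ground truth so
    every stage is testable without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
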
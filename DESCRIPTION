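Package: gestnet
Title: Stage-Resolved Transcriptome Clustering and Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a staged-pregnancy endometrial
    transcriptome workflow: RMA-style preprocessing (quantile normalization,
    median-polish probe summarization, log2 scale), baseline-versus-stage
    differential expression by Welch t-tests with Benjamini-Hochberg false
    discovery rate control, soft temporal clustering of differentially
    expressed genes by fuzzy c-means with data-driven selection of the
    cluster number and fuzzifier, weighted gene co-expression network
    construction with scale-free soft-threshold selection, topological
    overlap module detection and signed scaled-connectivity hub calling,
    and a 2^-ddCT qPCR validation stage with an FDR-filtered correlation
    network. Ships a synthetic-data generator with planted temporal
    archetypes, co-expression modules, hub genes and null genes so every
    stage can be exercised against recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    withr
Config/testthat/edition: 3
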
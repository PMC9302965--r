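Package: tidypeaks
Title: Consensus Peak Construction, QC, and Motif-Expression Integration
    for ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for the downstream layer of ATAC-seq analysis:
    fragment-size and signal-to-background quality control (nucleosomal size
    classes, TSS enrichment, FROT, FRiP), fixed-width consensus peak
    construction with score-per-million normalization and iterative overlap
    removal, cross-platform and cross-condition peak-set comparison under a
    40 percent feature-overlap rule, and integration of motif enrichment with
    gene expression to nominate candidate master transcription factors. A
    fully seeded synthetic-data generator emulates multi-replicate,
    multi-platform chromatin accessibility libraries with planted ground
    truth so every stage is testable without external downloads. All
    user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
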
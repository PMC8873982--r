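Package: cnvrkit
Title: Post-Calling Copy Number Variant Analysis for SNP-Array Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the downstream analysis of copy number variant (CNV)
    calls from SNP-array cohorts genotyped against one or more genome
    assemblies. Parses PennCNV and CNVPartition/GenomeStudio call lists,
    applies per-sample signal-quality and per-call length/gap filters, merges
    calls into population CNV regions (CNVRs) classified as gain, loss or
    mixed, compares calls and regions within and across callers and
    assemblies, derives frequency-threshold consensus CNVRs and consensus
    genes from refGene-style annotation, and contrasts SNP manifests between
    assembly versions. Ships a synthetic-cohort generator with a full ground
    truth manifest so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
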
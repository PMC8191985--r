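Package: hybridase
Title: Allele-Specific Expression Analysis of Reciprocal F1 Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects parent-of-origin (genomic imprinting) and species-of-origin
    (cis-regulatory) effects from allele-specific expression in reciprocal F1
    hybrids of two inbred lines. Provides fixed-difference SNP classification
    from jointly genotyped parental VCFs, SNP-substituted pseudo-reference
    construction to mitigate mapping bias, per-gene pooling of allele counts
    with depth and SNP-number filters, Fisher's exact test of allelic-ratio
    differences between reciprocal crosses with Benjamini-Hochberg FDR control,
    dual-reference expression QC, genetic-map coordinate conversion and
    introgression-marker scanning, and a fully seeded synthetic-data generator
    so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
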
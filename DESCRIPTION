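Package: retromethyl
Title: Locus- and Family-Level Methylation Analysis of LINE-1 and Alu
    Retrotransposons
Version: 0.1.0
Authors@R:
    person("retromethyl", "developers", email = "retromethyl@example.org",
           role = c("aut", "cre"))
Description: Tools for repetitive-element-centric analysis of CpG
    methylation arrays: annotation of array probes to LINE-1 and Alu
    repeats with family and evolutionary-age classification,
    total/family/locus-level differential methylation with
    Benjamini-Hochberg false discovery control, gene-region feature
    enrichment, cross-cohort Venn partitioning and variant-unique target
    locus selection, integration with multi-study expression results via
    an inverse-relationship filter, single-CpG ROC biomarker evaluation,
    and a seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
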
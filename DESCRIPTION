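Package: locop
Title: Local Gene Co-Expression Discovery, Genetic Control and Pleiotropy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies locally co-expressed gene pairs (COPs) from
    cross-individual expression matrices using per-gene permutation nulls
    with Benjamini-Hochberg FDR control, builds distance-matched non-COP
    and correlation-matched trans-COP controls, computes pair-level
    molecular-feature metrics (CTCF insulation, Hi-C contacts, enhancer
    sharing, transcription-factor binding, expression similarity, linkage
    disequilibrium, GO sharing, eQTL sharing) with a logistic-regression
    AUC evaluation harness, maps cis-eQTLs (nominal and permutation
    passes) and classifies eQTL sharing across gene pairs, runs
    permutation-based functional-annotation enrichment tests, and
    quantifies GWAS trait pleiotropy and genomic inflation. Ships a
    synthetic-data generator emulating the statistical structure of
    population-scale RNA-seq plus genotype studies so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    pROC,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
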
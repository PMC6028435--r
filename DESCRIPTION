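Package: degnet
Title: Paired Differential-Expression Screening and Pathway-Network Hub
    Discovery for Tumor/Adjacent-Normal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A discovery-to-validation pipeline for paired tumor versus
    adjacent-normal RNA-seq studies. Implements RPKM normalization with a
    mapped-gene expression filter, a per-pair fold-change and
    expression-difference screen for differentially expressed genes,
    hypergeometric term over-representation testing with Benjamini-Hochberg
    adjustment, construction of an integrated pathway regulatory network from
    KGML files with top-decile degree hub-gene selection, validation-cohort
    differential-expression and qPCR 2^-ddCt concordance checks,
    protein-protein interaction subnetwork extraction with chromosome
    co-location classification, and Spearman association of gene expression
    with ordinal clinical phenotypes. A seeded synthetic-data generator
    emulates every input so the full pipeline runs and is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
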
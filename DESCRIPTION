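Package: tRFtools
Title: Identification, Quantification and Cohort Analysis of tRNA-Derived
    Small RNA Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic pipeline for tRNA-derived small RNAs (tsRNAs /
    tRFs) in small-RNA-seq cohorts. Builds mature-tRNA, 5'-leader and
    3'-trailer reference spaces (intron splicing, CCA addition, histidine
    G-1), classifies candidate fragment sequences into the five canonical
    tRF classes by exhaustive exact matching, assigns tDRnamer-style
    identifiers, and quantifies fragments by full-length exact read
    matching. Cohort statistics cover empirical-Bayes moderated-t
    differential expression, median-split Kaplan-Meier survival with the
    log-rank test, Breslow partial-likelihood Cox regression, chi-square
    association with pathology categories, and Spearman top-k correlated
    genes; downstream modules provide hypergeometric over-representation
    and permutation GSEA against GMT gene sets, and a miRNA-like seed-match
    plus duplex-score scanner for 3'UTR target prediction. A seeded
    synthetic-data module emulates every pipeline input so all stages are
    testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    survival,
    optparse
Config/testthat/edition: 3
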
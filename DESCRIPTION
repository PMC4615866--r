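Package: smapipe
Title: Sex-Methylation Association Discovery, Replication and Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epigenome-wide association workflow for autosomal DNA
    methylation differences between men and women measured on Illumina
    450k-style beta-value arrays. Provides allosomal cross-hybridization
    screening of probe sequences, covariate-residualized sex-methylation
    correlation with Bonferroni control, Fisher-z DerSimonian-Laird
    random-effects meta-analysis across replication cohorts, genomic-context
    (CpG island shore), imprinted-gene, probe-count-bias-corrected
    (Wallenius noncentral hypergeometric) and plain gene-set enrichment
    tests, cis methylation-expression linkage models, and a multi-cohort
    synthetic-data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
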
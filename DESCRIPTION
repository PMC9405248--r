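Package: isomiRtand
Title: Serum isomiR and miRNA Biomarker Discovery for Neuropsychiatric
    Outcome Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for small-RNA biomarker discovery in
    serum cohorts stratified by neuropsychiatric outcome (control,
    intellectual disability, autism spectrum disorder, or both).
    Enumerates the combinatorial isomiR variant space of canonical
    mature miRNAs (non-templated 5'/3' extensions of one to three
    bases and 3' trimming down to 18 nt), quantifies variants by
    exact-match assignment of quality- and adapter-trimmed reads,
    performs median-of-ratios normalisation and negative-binomial Wald
    differential expression with Benjamini-Hochberg control, screens
    reference-gene-ratio features by ROC/AUC with Youden-threshold
    operating points and permutation robustness tests, and selects
    multi-marker panels by L1-penalised logistic regression.  A
    synthetic-cohort generator (group-structured negative-binomial
    counts with planted effects, and read-level FASTQ emission)
    supports end-to-end validation when patient data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    glmnet,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
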
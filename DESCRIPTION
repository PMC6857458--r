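Package: dmrkit
Title: Sliding-Window Differential Methylation Analysis for 450K-Style Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end differential DNA-methylation analysis for Illumina
    450K-style beta-value matrices in small case/control cohorts stratified by
    age: probe filtering, beta/M-value transforms, empirical-Bayes moderated
    linear models with a genotype-by-age interaction contrast,
    differentially methylated region (DMR) calling by 1-kb sliding windows
    aggregated with Fisher's method, CpG-feature and gene-set enrichment,
    an age-corrected extreme-delta-beta phenotype contrast, and a
    LASSO-penalized logistic biomarker model with leave-one-out
    cross-validation, ROC/AUC and the DeLong test. Includes a synthetic-data
    generator that emulates the cohort structure these analyses assume, so
    the whole pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    glmnet,
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
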
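Package: agesig
Title: Healthy-Ageing Transcriptomic Signature Discovery and Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and applying rank-based transcriptomic
    signatures of healthy ageing. Implements nested leave-one-out
    cross-validated feature selection with empirical-Bayes moderated
    t-ranking and k-nearest-neighbour classification, external-validation
    classification with ROC/AUC evaluation, a direction-aware median-rank
    per-sample gene score with non-parametric group statistics,
    hypergeometric gene-set enrichment against a resampling null, and a
    synthetic-cohort generator so that every stage of the pipeline can be
    exercised end-to-end without access to the original microarray cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
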
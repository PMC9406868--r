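Package: m6aScore
Title: Consensus Subtyping and PCA-Based Scoring of m6A Regulators in
    Prostate Cancer Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-usable pipeline for N6-methyladenosine (m6A) regulator
    analysis of bulk prostate-cancer expression cohorts: Mann-Whitney
    screening of regulators between tumor and normal tissue, resampled
    consensus clustering of tumors with CDF/delta-area selection of the
    cluster number, silhouette and SigClust cluster validation, pairwise
    differential-expression signatures with Benjamini-Hochberg control, a
    PCA-derived per-sample m6A score built on metastasis-associated
    regulators, and evaluation of the score against metastasis (ROC/AUC),
    Gleason grade (ANOVA), survival (Kaplan-Meier and log-rank) and a
    rank-based stemness index. A seeded synthetic-cohort generator with
    latent tumor subtypes, metastasis labels and censored survival makes
    every stage testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    stats,
    survival,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
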
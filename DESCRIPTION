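Package: ionstim
Title: Metal-Ion-Stimulation Glioma Subtyping, Risk Modelling and
    Shapley-Guided Grade Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying glioma transcriptomes through the lens of a
    metal-ion-stimulation gene signature: Welch-t differential expression with
    logFC/FDR cutoffs and signature intersection, from-scratch Monti-style
    consensus clustering to discover response subtypes (M1/M2), a tSNE-sum
    per-sample response score, univariate and multivariate Cox screening with a
    gene-expression risk score (median split, Kaplan-Meier, log-rank and IPCW
    time-dependent ROC), dual feature selection over boosted-tree models
    (recursive feature elimination and Shapley-attribution ranking) with
    per-gene logistic diagnostic AUC, and a hybrid grade classifier that
    clusters Shapley attributions of a tuned boosted-tree model with K-means
    and benchmarks it against the base model over repeated splitting schemes.
    A seeded synthetic-data generator reproduces the statistical structure the
    pipeline assumes, so every stage is testable end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    xgboost,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    cluster,
    randomForest,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
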
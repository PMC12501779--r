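Package: brcaIS
Title: Cohort-Aware Intrinsic Molecular Subtyping for Breast Cancer
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A unified framework for breast-cancer intrinsic molecular
    subtyping (Luminal A, Luminal B, HER2-enriched, Basal-like, Normal-like)
    from bulk expression data. Provides nearest-centroid classification with
    a family of cohort-centering strategies (median, robust quantile
    rescaling, IHC-guided subcohort centering, PCA-guided centering,
    subgroup-specific quantile centering), a single-sample predictor engine
    based on within-sample gene-pair rules scored by a naive-Bayes model,
    method-specific normalization for raw RNA-seq counts (upper-quartile
    log2-CPM and linear FPKM routes), Entrez-based probe-to-gene mapping,
    a quantitative cohort-composition-aware method selector with an audited
    decision trail, inter-classifier concordance statistics (Shannon
    entropy, Cohen's kappa), a synthetic cohort simulator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
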
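Package: thalrisk
Title: Hybrid AHP-TOPSIS and Machine Learning Toolkit for Thalassemia Risk
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for expert-informed risk assessment of thalassemia carrier
    status from tabular survey cohorts. Implements Analytic Hierarchy Process
    (AHP) weight derivation with full consistency diagnostics, per-patient
    TOPSIS relative-closeness scoring and Pareto-style risk stratification,
    hybrid feature-importance fusion (impurity-based and univariate F scores),
    a leakage-safe stratified cross-validation harness for classifier
    benchmarking with and without multi-criteria weighting, tree-SHAP based
    attribution with Kruskal-Wallis and pairwise Mann-Whitney significance
    testing, and a synthetic-cohort generator emulating the carrier versus
    non-carrier shifts in hematologic indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    grDevices,
    graphics,
    xgboost
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
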
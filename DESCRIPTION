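Package: siteclass
Title: Site-Aware Case-Control Classification for Multi-Site ROI Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating machine-learning case-control classifiers on
    multi-site regional-brain-measure tables of the kind produced by FreeSurfer
    consortium pipelines. Implements site-stratified, leave-one-site-out and
    size-matched cross-validation designs, in-fold robust preprocessing with
    train-median imputation, four covariate-handling regimes including
    train-fitted confound residualization, rank-based AUC with Mann-Whitney
    significance and Hanley-McNeil confidence intervals, permutation feature
    importance with per-fold false-discovery-rate control, clinical subgroup
    contrasts with intersected-split sensitivity reruns, and a synthetic
    multi-site cohort generator with controllable site, diagnosis and
    medication effects for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    glmnet,
    kernlab,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
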
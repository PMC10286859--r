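Package: akiphen
Title: Drug-Anchored KDIGO Acute Kidney Injury Phenotyping and Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adjudicates acute kidney injury (AKI) from longitudinal inpatient
    serum-creatinine series using the KDIGO creatinine criteria anchored at the
    first dose of a target drug (a 26.5 umol/L rise within 48 hours, or a
    1.5-fold rise within 7 days), with exclusion of pre-admission and pre-drug
    episodes. Provides the downstream pharmacoepidemiology analysis: Pearson
    chi-squared and Wilcoxon rank-sum univariate screening, multivariate
    logistic regression with Wald odds ratios and confidence intervals,
    stratified 10-fold cross-validated out-of-fold scoring, and ROC/AUC
    evaluation with DeLong confidence intervals and a Youden-index operating
    point. A seeded synthetic electronic-health-record cohort generator with
    known ground truth makes every pipeline stage testable without access to
    hospital records.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
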
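# akiphen

Drug-anchored KDIGO acute-kidney-injury (AKI) phenotyping and risk modelling
for inpatient pharmacoepidemiology.

Retrospective drug-safety studies need a reproducible rule that turns an
inpatient's irregular serum-creatinine record into an AKI adjudication
attributable to a target drug, and then a standard analysis stack on top of
it. `akiphen` provides both, for analysts working with longitudinal
inpatient tables (patients, timestamped creatinine, drug-exposure windows,
comorbidity/co-medication covariates):

* **Adjudication** (`adjudicate()`, `adjudicate_cohort()`): a patient is
  AKI-positive after the drug when, among the baseline (most recent sCr at or
  before the first dose) and all later in-admission measurements, some later
  value rises by ≥ 26.5 µmol/L above *any* earlier value within 48 h, or
  reaches ≥ 1.5× any earlier value within 7 days (KDIGO creatinine criteria,
  inclusive comparisons, all ordered pairs in the window). Patients with a
  pre-admission AKI diagnosis, or whose series already satisfies a criterion
  before the first dose, are excluded as non-drug-attributable; patients
  without a baseline or without post-dose measurements are unassessable.
  A brute-force pair-enumeration oracle (`brute_force_adjudicate()`) backs
  the fast scanner in the test suite.
* **Univariate screening** (`screen()`): uncorrected Pearson chi-squared for
  categorical variables, Wilcoxon rank-sum for continuous ones, raw
  p < 0.05 gate (optional Benjamini–Hochberg).
* **Risk model** (`fit_logistic()`, `wald_table()`,
  `cross_validated_scores()`, `roc_auc()`): logistic regression by IRLS
  maximum likelihood with Wald odds ratios exp(β) and 95% CIs
  exp(β ± 1.96·SE); stratified, seeded 10-fold cross-validation with pooled
  out-of-fold scoring; Mann–Whitney AUC with DeLong CI and the
  Youden-index operating point.
* **Synthetic EHR generator** (`simulate_cohort()`): a seeded cohort with
  known covariate→risk logistic model, injected creatinine episodes and
  known ground truth, so every stage is testable without hospital records.
* **Orchestration** (`run_pipeline()`): simulate → detect → screen → fit →
  report, with csv stage outputs and a JSON manifest of digests. A thin
  command-line wrapper lives at `inst/cli/akiphen.R`.

## Worked example

```r
library(akiphen)

sim <- simulate_cohort(simulation_config(n_patients = 2000, rng_seed = 42))
adj <- adjudicate_cohort(sim$cohort)
table(adj$status)
#>          AKI_POST_DRUG EXCLUDED_PRE_ADMISSION  EXCLUDED_PRE_DRUG_AKI
#>                    244                     52                     39
#>                 NO_AKI           UNASSESSABLE
#>                   1663                      2

inc <- cohort_incidence(adj)   # excluded/unassessable are not in the denominator
sprintf("incidence: %.2f%% (%d/%d)", 100 * inc$proportion, inc$n_aki, inc$n_analyzable)
#> "incidence: 12.79% (244/1907)"

keep <- adj$status %in% c("AKI_POST_DRUG", "NO_AKI")
lab  <- as.integer(adj$status[keep] == "AKI_POST_DRUG")
cov  <- sim$cohort$covariates[match(adj$patient_id[keep], sim$cohort$covariates$patient_id), ]
scr  <- screen(cov, lab)                      # chi2 / wilcoxon per variable, p < 0.05 gate
x    <- as.matrix(cov[, scr$variable[scr$selected]])
cfg  <- analysis_config(rng_seed = 42)
wald_table(fit_logistic(x, lab, cfg))         # beta, Wald, OR (95% CI), p per variable
#>      variable   beta     se wald    or ci_low ci_high  p_value
#>     diuretics 1.1336 0.1590 50.8 3.107  2.275    4.24 1.01e-12   (planted log-OR: 1.19)
#>     ...

roc <- roc_auc(cross_validated_scores(x, lab, cfg), lab)
roc
#> ROC: AUC 0.780 (95% CI 0.749-0.811), n = 244 cases / 1663 controls
#> Youden operating point: threshold 0.1586, sensitivity 62.7%, specificity 79.1%
```

The adjudicated incidence recovers the generator's 12% target; the fitted
diuretics odds ratio (3.11) sits near its planted value (exp(1.19) = 3.29,
attenuated slightly by detection noise in the outcome labels); and the
cross-validated AUC is reported with a DeLong interval from pooled
out-of-fold scores. `vignettes/akiphen-methods.Rmd` documents the model,
the tie-break and window conventions, the generator's assumptions and the
package's known limitations.

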
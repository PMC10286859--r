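---
title: "Drug-anchored KDIGO AKI phenotyping and risk modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-anchored KDIGO AKI phenotyping and risk modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(akiphen)
```

## The phenotyping problem

Retrospective drug-safety studies of nephrotoxic antimicrobials need a
reproducible rule that turns an inpatient's irregular serum-creatinine (sCr)
record into a yes/no adjudication of drug-associated acute kidney injury
(AKI). `akiphen` implements the KDIGO creatinine criteria anchored at the
first dose of the drug under study, and the analysis stack a
pharmacoepidemiology cohort study builds on top of the adjudication:
univariate screening, multivariate logistic regression, and cross-validated
ROC evaluation.

## The adjudication rule

All creatinine is canonicalized to µmol/L (1 mg/dL = 88.4 µmol/L) and sorted
in time; tied-time duplicates with equal values collapse to one measurement,
and tied times with differing values are rejected at load. A patient is
adjudicated `AKI_POST_DRUG` when, among the *candidate series* — the baseline
measurement plus every measurement after the first dose and up to discharge —
some later value $v_j$ satisfies either criterion against *any* earlier value
$v_i$ in the candidate series:

* **absolute**: $v_j - v_i \ge 26.5$ µmol/L with $t_j - t_i \le 48$ h, or
* **ratio**: $v_j / v_i \ge 1.5$ with $t_j - t_i \le 7$ days.

Both comparisons are inclusive (≥) and both windows are closed at both ends;
this is the conservative reading of the KDIGO wording, which states the
thresholds but not an endpoint convention. Only rises count: decreases never
trigger. Every ordered pair inside the window is compared, not just adjacent
pairs and not only the baseline, because a mid-stay dip followed by a rapid
rebound is exactly the pattern the 48-hour criterion exists to catch.

The **baseline** is the most recent measurement at or before the first dose
(a draw at the dose timestamp counts as pre-dose). The reported onset is the
later measurement of the earliest qualifying pair — minimal later time across
both criteria, the absolute criterion winning an exact tie, and among earlier
partners of that later time the largest rise, then the earliest partner. The
tie-breaks are arbitrary but fixed, so adjudications are reproducible.

Two exclusion rules run first: a pre-admission AKI flag excludes the patient
outright (`EXCLUDED_PRE_ADMISSION`), and either criterion firing on the
measurements strictly before the first dose attributes the episode to causes
other than the drug (`EXCLUDED_PRE_DRUG_AKI`). Patients with no pre-dose
baseline or no post-dose measurement are `UNASSESSABLE`; they are excluded
from incidence and modelling rather than counted as non-AKI, since counting
them as negatives would bias incidence downward. Urine-output criteria are
out of scope: continuous urine monitoring is rarely recorded reliably in
retrospective inpatient data.

One consequence of the baseline definition is worth stating explicitly:
adding a *post-dose* measurement can never withdraw an AKI verdict (existing
qualifying pairs persist; this is tested as a property), but inserting a new
*pre-dose* measurement closer to the first dose replaces the baseline and can
legitimately change the verdict, because the comparator itself changes. That
is intended semantics — the baseline is "the most recent value before first
use" — not an instability.

A deliberately naive quadratic reference implementation
(`brute_force_adjudicate()`) enumerates every ordered pair with no early
exit; the fast scanner is required to agree with it exactly on thousands of
randomized series in the test suite.

## Univariate screening

Categorical variables are tested with the uncorrected Pearson chi-squared
statistic $\sum (O-E)^2/E$ (no Yates correction — recomputing published
contingency rows from their printed counts matches the printed statistics
only without correction, so that convention is adopted); continuous variables
with the Wilcoxon rank-sum test, using mid-ranks for ties and the exact null
distribution for small tie-free samples, otherwise a tie-corrected normal
approximation with continuity correction. Variables with raw $p < \alpha$
(default 0.05) enter the multivariate model. No multiple-testing adjustment
is applied at this stage by default — that mirrors the screening convention
of the studies this pipeline reproduces — but a Benjamini–Hochberg gate is
available (`p_adjust = "BH"`). A variable constant across patients is
reported unselected with a warning rather than failing the screen.

## Risk model and evaluation

The logistic model is fitted by Newton–Raphson/IRLS on the Bernoulli
log-likelihood, converged when the log-likelihood changes by less than
`tol` (default 1e-8, default cap 50 iterations). Standard errors come from
the inverse observed information at the optimum; each variable is reported
as β, the Wald statistic $(\beta/\mathrm{SE})^2$, the odds ratio
$e^\beta$ and its CI $e^{\beta \pm z_{0.975}\mathrm{SE}}$. Apparent
separation (a coefficient escaping ±30 before the likelihood settles) and
non-convergence raise typed errors instead of returning unreliable
estimates. Continuous predictors enter untransformed by default so odds
ratios are per unit; standardization is an option.

Validation uses stratified 10-fold cross-validation: within each outcome
class a seeded permutation is dealt round-robin, every patient is scored
exactly once by a model not trained on them, and the pooled out-of-fold
scores feed the ROC. Pooling (rather than per-fold averaging) is used
because it is tie-free and reproducible. The AUC is the tie-corrected
Mann–Whitney statistic; its CI uses DeLong's placement-variance estimator
(deterministic, no resampling). The reported operating point maximizes
Youden's $J$, ties broken toward the highest threshold. Class imbalance is
handled by unweighted maximum likelihood by default, with inverse-prevalence
class weights as an option; neither is claimed to match any particular
published study's (unstated) handling.

## What the synthetic cohort emulates

`simulate_cohort()` generates, from one seeded stream, a cohort whose
statistical structure matches what the pipeline assumes: binary
comorbidity/co-medication covariates drawn independently at prevalences of
the order seen in inpatient antimicrobial cohorts (hypertension 0.42,
pneumonia 0.27, diuretics 0.47, ...); AKI assigned by a known logistic model
whose nonzero log odds-ratios sit on the clinically established risk factors
(diuretics 1.19, pneumonia 0.47, cerebral apoplexy 0.33, heart failure 0.42,
sepsis 0.83, PPI 0.35, CRRT 1.76), with the intercept calibrated by
root-finding so the marginal incidence hits its target (default 0.12, the
range reported for these drugs being roughly 9–13%); baseline creatinine
log-normal with median 70 µmol/L and σ_log 0.25, +14% for males and
+0.2%/year past age 60; draws at exponential gaps (mean 24 h) with 5%
multiplicative log-normal measurement noise; and AKI episodes injected as a
linear rise to a plateau (peak fold-rise uniform on 1.6–2.5, reached within
12–48 h, onset 12–96 h after the first dose, with a guaranteed draw at the
peak). Two percent of patients carry a pre-admission AKI flag and two
percent receive a pre-dose episode (with a correspondingly later first dose)
to exercise both exclusion paths. Length of stay and cost are log-normal
with a mild AKI shift in the direction seen in real cohorts.

What it does **not** emulate: covariate correlation (a hook accepts only
independent prevalences by default — real comorbidities cluster),
pharmacokinetics or dose–response, creatinine-lowering interventions such as
CRRT (present only as a covariate flag), informative sampling (sicker
patients being drawn more often), or missingness. Passing end-to-end tests
therefore demonstrates that the *pipeline machinery* is correct under known
ground truth, not that any particular clinical effect estimate transfers to
real records.

Recovery tests of the planted coefficients run on ground-truth outcome
labels: they check the screen/fit/CV stack. Running the detector in the loop
adds non-differential outcome misclassification whose attenuation is a
property of phenotyping, not of the estimator; detector accuracy is measured
separately against ground truth.

## Numerical choices and known limitations

* The detection threshold stays 26.5 µmol/L; the mg/dL form 0.3 converts to
  26.52, so data recorded in mg/dL is very slightly more permissive at the
  boundary. Documented, not "fixed".
* Under 5% multiplicative noise the fixed absolute threshold has a
  noise-driven false-positive rate on high-baseline patients: a 26.5 µmol/L
  rise is only ≈2.3 pair-noise standard deviations when baseline exceeds
  ≈100 µmol/L. Measured at dense (q6h) sampling this contributes ≈2–3%
  overall false positives, essentially all in that stratum (<0.2% below a
  baseline of 100). This is a property of the criterion itself, shared by
  any implementation of it.
* Rare planted effects (CRRT, sepsis at ~1% prevalence) carry Wald standard
  errors near 0.18 even at n = 20000, so end-to-end recovery is asserted
  within the larger of 0.15 and three standard errors.
* Timestamps are ISO 8601 at minute resolution; sub-minute structure is not
  represented.
* Test and acceptance problem sizes — up to 20000 simulated patients for
  end-to-end recovery, 8767 (the published cefoperazone cohort size) for the
  pipeline rerun, 1000 replicates for oracle-equivalence and null
  calibration — were chosen as the smallest sizes at which the stochastic
  checks have comfortable power.
* The published headline AUCs and incidences for the two antimicrobial
  cohorts cannot be recomputed here: they require the hospital's
  patient-level records, which are not public. The package reproduces every
  printed statistic that is an arithmetic identity of printed counts or
  coefficients, and validates everything else by property-based simulation.
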
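# End-to-end orchestration and paper-style summary tables.
#
# run_pipeline(): simulate -> detect -> screen -> fit (with 10-fold CV and
# ROC) -> report, writing each stage's output as csv plus a JSON run manifest
# with file digests so every reported number is traceable and a rerun with
# the same config and seed reproduces identical digests.

fmt_count_pct <- function(count, group_total) {
  sprintf("%d (%.2f%%)", count, 100 * count / group_total)
}

#' Baseline characteristics table with group tests
#'
#' Renders the cohort-description table: counts and percentages of the
#' demographic variables per AKI group with the chi-squared statistic, and
#' medians (min, max) with the Wilcoxon rank-sum statistic for length of stay
#' and hospital cost. Statistics are computed by the same screening functions
#' used elsewhere, so the rendered table is a pure view of stage outputs.
#'
#' @param cohort an `aki_cohort`.
#' @param adjudications data.frame from [adjudicate_cohort()].
#' @return data.frame with columns `variable`, `level`, `aki`, `non_aki`,
#'   `total`, `statistic`, `p_value`.
#' @export
make_baseline_table <- function(cohort, adjudications) {
  keep <- adjudications$status %in% c("AKI_POST_DRUG", "NO_AKI")
  adj <- adjudications[keep, , drop = FALSE]
  pat <- cohort$patients[match(adj$patient_id, cohort$patients$patient_id), ]
  aki <- adj$status == "AKI_POST_DRUG"
  if (!any(aki) || all(aki)) {
    stop_akiphen("empty_group", "both AKI and non-AKI groups must be nonempty")
  }
  n1 <- sum(aki)
  n0 <- sum(!aki)

  cov <- cohort$covariates[match(adj$patient_id, cohort$covariates$patient_id), ]
  cat_row <- function(variable, x) {
    lev <- if (is.factor(x)) levels(x) else sort(unique(x))
    tab <- table(factor(aki, levels = c(TRUE, FALSE)), factor(x, levels = lev))
    res <- pearson_chi2(unclass(tab))
    data.frame(
      variable = variable, level = lev,
      aki = fmt_count_pct(tab[1, ], n1),
      non_aki = fmt_count_pct(tab[2, ], n0),
      total = fmt_count_pct(colSums(tab), n1 + n0),
      statistic = c(res$statistic, rep(NA_real_, length(lev) - 1)),
      p_value = c(res$p_value, rep(NA_real_, length(lev) - 1)),
      stringsAsFactors = FALSE
    )
  }
  cont_row <- function(variable, x) {
    res <- wilcoxon_rank_sum(x[aki], x[!aki])
    fmt <- function(v) sprintf("%.2f (%.2f, %.2f)", stats::median(v), min(v), max(v))
    data.frame(
      variable = variable, level = "",
      aki = fmt(x[aki]), non_aki = fmt(x[!aki]), total = fmt(x),
      statistic = res$rank_sum, p_value = res$p_value,
      stringsAsFactors = FALSE
    )
  }
  rows <- list(
    cat_row("sex", pat$sex),
    cat_row("age_group", pat$age_group)
  )
  if ("smoking" %in% names(cov)) {
    rows <- c(rows, list(cat_row("smoking", cov$smoking)))
  }
  rows <- c(rows, list(
    cont_row("length_of_stay_days", pat$los_days),
    cont_row("hospital_cost", pat$cost)
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages, in order: simulate the cohort, adjudicate AKI, univariate screen,
#' multivariate logistic fit with stratified 10-fold cross-validated scoring
#' and ROC/AUC, and render the baseline table. All stage outputs are written
#' as csv under `out_dir` together with `manifest.json` (config snapshot,
#' seeds, per-file md5 digests). Identical config and seed yield identical
#' digests.
#'
#' @param sim_config a [simulation_config()].
#' @param analysis a [analysis_config()].
#' @param out_dir output directory.
#' @return list with `manifest`, `adjudications`, `incidence`,
#'   `screen_results`, `fit`, `wald`, `roc`, `baseline_table`.
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         analysis = analysis_config(),
                         out_dir = tempfile("akiphen_run")) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_akiphen("stage", sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_stage <- function(...) message(sprintf("[akiphen %s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))

  log_stage("stage 1/5: simulate (n = %d, seed = %d)", sim_config$n_patients, sim_config$rng_seed)
  sim <- stage("simulate", simulate_cohort(sim_config))
  write_simulation(sim, file.path(out_dir, "cohort"))

  log_stage("stage 2/5: detect")
  adj <- stage("detect", adjudicate_cohort(sim$cohort))
  utils::write.csv(adj, file.path(out_dir, "adjudications.csv"), row.names = FALSE, quote = FALSE)
  inc <- cohort_incidence(adj)

  log_stage(
    "stage 3/5: screen (incidence %.2f%%, %d/%d)",
    100 * inc$proportion, inc$n_aki, inc$n_analyzable
  )
  keep <- adj$status %in% c("AKI_POST_DRUG", "NO_AKI")
  labels <- as.integer(adj$status[keep] == "AKI_POST_DRUG")
  cov <- sim$cohort$covariates[
    match(adj$patient_id[keep], sim$cohort$covariates$patient_id), ,
    drop = FALSE
  ]
  scr <- stage("screen", screen(cov, labels, alpha = analysis$alpha))
  utils::write.csv(scr, file.path(out_dir, "screen.csv"), row.names = FALSE, quote = FALSE)

  selected <- scr$variable[scr$selected]
  log_stage("stage 4/5: fit (%d selected variables, %d-fold CV)", length(selected), analysis$n_folds)
  x <- as.matrix(cov[, selected, drop = FALSE])
  fit <- stage("fit", fit_logistic(x, labels, analysis))
  wt <- wald_table(fit)
  utils::write.csv(wt, file.path(out_dir, "coefficients.csv"), row.names = FALSE, quote = FALSE)
  scores <- stage("cross_validate", cross_validated_scores(x, labels, analysis))
  roc <- stage("roc", roc_auc(scores, labels, ci_level = analysis$ci_level))
  utils::write.csv(roc$points, file.path(out_dir, "roc_points.csv"), row.names = FALSE, quote = FALSE)

  log_stage("stage 5/5: report (AUC %.3f)", roc$auc)
  bl <- stage("report", make_baseline_table(sim$cohort, adj))
  utils::write.csv(bl, file.path(out_dir, "baseline_table.csv"), row.names = FALSE, quote = FALSE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  digests <- tools::md5sum(files)
  names(digests) <- sub(paste0("^", out_dir, "/?"), "", names(digests))
  manifest <- list(
    tool = paste0("akiphen ", as.character(utils::packageVersion("akiphen"))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    seeds = list(simulation = sim_config$rng_seed, analysis = analysis$rng_seed),
    sim_config = unclass(sim_config),
    analysis_config = unclass(analysis),
    stages = c("simulate", "detect", "screen", "fit", "report"),
    digests = as.list(digests)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  list(
    manifest = manifest, adjudications = adj, incidence = inc,
    screen_results = scr, fit = fit, wald = wt, roc = roc,
    baseline_table = bl, out_dir = out_dir
  )
}
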
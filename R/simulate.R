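# Seeded synthetic inpatient-cohort generator with known ground truth.
#
# Emulates the statistical structure the pipeline assumes: irregularly
# sampled creatinine series around a first-dose anchor, binary covariates at
# prevalences of the order seen in hospital nephrotoxicity cohorts, AKI
# assigned by a known logistic model on those covariates with a target
# marginal incidence near 10-13%, creatinine episodes injected as a linear
# rise to a plateau, and configurable fractions of pre-admission and
# pre-drug AKI cases to exercise the exclusion rules.

#' Simulation configuration
#'
#' Defaults define the reference synthetic study conditions: covariate
#' prevalences of the order printed for inpatient antimicrobial cohorts,
#' planted log odds-ratios on the clinically established risk factors
#' (diuretics, pneumonia, cerebral apoplexy, heart failure, sepsis, PPI,
#' CRRT), a 12% target marginal AKI incidence, log-normal baseline creatinine
#' (median 70 umol/L, sigma_log 0.25, +14% for males, +0.2%/year past 60),
#' exponential sampling gaps with 24 h mean, 5% multiplicative measurement
#' noise, and detectable episodes (peak fold-rise 1.6-2.5 reached within
#' 12-48 h, onset 12-96 h after the first dose).
#'
#' @param n_patients cohort size.
#' @param rng_seed integer seed driving every draw.
#' @param drug drug under study.
#' @param prevalence named vector of binary-covariate prevalences in (0, 1).
#' @param beta_true named vector of true log odds-ratios (names must be a
#'   subset of `names(prevalence)`).
#' @param target_incidence target marginal P(AKI); the intercept is
#'   calibrated to hit it (ignored when `intercept` is given).
#' @param intercept optional fixed intercept on the logit scale.
#' @param baseline_scr_median,baseline_scr_sdlog log-normal baseline
#'   creatinine parameters (umol/L).
#' @param sampling_gap_hours mean creatinine inter-measurement gap.
#' @param noise_sigma sigma of the multiplicative log-normal measurement noise.
#' @param onset_delay_hours,peak_fold,rise_hours uniform ranges for episode
#'   onset delay after the first dose, peak fold-rise and rise time.
#' @param frac_pre_admission,frac_pre_drug fractions of patients generated as
#'   pre-admission-flagged and pre-drug-episode exclusion cases.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 2000,
                              rng_seed = 1L,
                              drug = "cefoperazone_sulbactam",
                              prevalence = default_prevalence(),
                              beta_true = default_beta_true(),
                              target_incidence = 0.12,
                              intercept = NULL,
                              baseline_scr_median = 70,
                              baseline_scr_sdlog = 0.25,
                              sampling_gap_hours = 24,
                              noise_sigma = 0.05,
                              onset_delay_hours = c(12, 96),
                              peak_fold = c(1.6, 2.5),
                              rise_hours = c(12, 48),
                              frac_pre_admission = 0.02,
                              frac_pre_drug = 0.02) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_akiphen("prevalence", "prevalences must lie strictly in (0, 1)")
  }
  if (!all(names(beta_true) %in% names(prevalence))) {
    stop_akiphen("beta_true", "beta_true names must be a subset of prevalence names")
  }
  stopifnot(
    n_patients >= 2, noise_sigma > 0, sampling_gap_hours > 0,
    peak_fold[1] > 1, target_incidence > 0, target_incidence < 1
  )
  structure(
    list(
      n_patients = as.integer(n_patients), rng_seed = as.integer(rng_seed),
      drug = drug, prevalence = prevalence, beta_true = beta_true,
      target_incidence = target_incidence, intercept = intercept,
      baseline_scr_median = baseline_scr_median,
      baseline_scr_sdlog = baseline_scr_sdlog,
      sampling_gap_hours = sampling_gap_hours, noise_sigma = noise_sigma,
      onset_delay_hours = onset_delay_hours, peak_fold = peak_fold,
      rise_hours = rise_hours,
      frac_pre_admission = frac_pre_admission, frac_pre_drug = frac_pre_drug
    ),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @export
default_prevalence <- function() {
  c(
    hypertension = 0.42, diabetes = 0.23, cerebral_apoplexy = 0.31,
    anemia = 0.11, coronary_heart_disease = 0.27, pneumonia = 0.27,
    shock = 0.05, sepsis = 0.01, heart_failure = 0.07,
    skin_tissue_infection = 0.008, neoplastic_disease = 0.25, gout = 0.007,
    chronic_renal_insufficiency = 0.033, pancreatitis = 0.035, copd = 0.026,
    hypokalemia = 0.046, hyponatremia = 0.033, cirrhosis = 0.049,
    hyperlipidemia = 0.019,
    nsaids = 0.32, arb = 0.15, acei = 0.056, ppi = 0.32,
    aminoglycoside = 0.18, diuretics = 0.47,
    crrt = 0.01, mechanical_ventilation = 0.05, smoking = 0.34
  )
}

#' @rdname simulation_config
#' @export
default_beta_true <- function() {
  c(
    diuretics = 1.19, pneumonia = 0.47, cerebral_apoplexy = 0.33,
    heart_failure = 0.42, sepsis = 0.83, ppi = 0.35, crrt = 1.76
  )
}

#' Inject an AKI episode into a creatinine series
#'
#' Scales values from `onset` along a linear-rise-then-plateau envelope: the
#' multiplier grows linearly from 1 at onset to `peak_fold` after
#' `rise_hours`, and stays at `peak_fold` thereafter. Pre-onset values are
#' untouched. An onset after the last measurement is a no-op with a warning.
#'
#' @param series data.frame with `time` (POSIXct or numeric hours) and
#'   `value` columns.
#' @param onset episode onset time (same scale as `series$time`).
#' @param peak_fold peak multiplier (> 1 for a real episode; 1 is identity).
#' @param rise_hours time to reach the peak.
#' @return the series with post-onset values scaled.
#' @export
inject_aki_episode <- function(series, onset, peak_fold, rise_hours) {
  stopifnot(peak_fold >= 1, rise_hours >= 0)
  t <- as_hours(series$time)
  if (!nrow(series) || as_hours(onset) > max(t)) {
    warn_akiphen("episode_after_series", "episode onset after last measurement; series unchanged")
    return(series)
  }
  dt <- t - as_hours(onset)
  frac <- pmin(1, pmax(0, if (rise_hours > 0) dt / rise_hours else as.numeric(dt >= 0)))
  frac[dt < 0] <- 0
  series$value <- series$value * (1 + (peak_fold - 1) * frac)
  series
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

floor_minute <- function(x) as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")

#' Simulate a synthetic inpatient cohort with known ground truth
#'
#' Deterministic given `config$rng_seed`. Binary covariates are drawn
#' independently at their stated prevalences; the AKI indicator is Bernoulli
#' on the logistic of the planted linear predictor (intercept calibrated so
#' the marginal incidence matches `target_incidence`); episodes are injected
#' into post-dose creatinine for AKI patients; pre-admission-flagged and
#' pre-drug-episode exclusion cases are generated at the configured
#' fractions (pre-drug cases receive a later first dose so the pre-dose
#' episode is observable).
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (an `aki_cohort`) and `ground_truth` (a
#'   data.frame: `patient_id`, `category` of standard/pre_admission/pre_drug,
#'   `true_aki`, `true_onset`, `linear_predictor`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  with_rng_seed(config$rng_seed, {
    pid <- sprintf("P%05d", seq_len(n))
    sex <- ifelse(stats::rbinom(n, 1, 0.63) == 1L, "male", "female")
    age <- pmin(pmax(round(stats::rnorm(n, 63, 16)), 18), 97)
    admission <- floor_minute(
      as.POSIXct("2018-01-01 00:00", tz = "UTC") + stats::runif(n, 0, 1095) * 86400
    )

    flags <- vapply(
      names(config$prevalence),
      function(f) stats::rbinom(n, 1, config$prevalence[[f]]),
      integer(n)
    )
    X <- flags[, names(config$beta_true), drop = FALSE]
    xb <- drop(X %*% config$beta_true)
    b0 <- if (!is.null(config$intercept)) {
      config$intercept
    } else {
      f <- function(b) mean(stats::plogis(b + xb)) - config$target_incidence
      lo <- f(-30)
      hi <- f(30)
      if (lo > 0 || hi < 0) {
        stop_akiphen("incidence_unreachable", sprintf(
          "target incidence %.3f unreachable; achievable range with given beta_true: (%.4f, %.4f)",
          config$target_incidence, config$target_incidence + lo, config$target_incidence + hi
        ))
      }
      stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    }
    lp <- b0 + xb
    true_aki <- stats::rbinom(n, 1, stats::plogis(lp)) == 1L

    # exclusion cases: generated independently of the planted outcome
    u <- stats::runif(n)
    category <- rep("standard", n)
    category[u < config$frac_pre_admission] <- "pre_admission"
    category[u >= config$frac_pre_admission &
      u < config$frac_pre_admission + config$frac_pre_drug] <- "pre_drug"
    true_aki[category != "standard"] <- FALSE

    dose_offset <- stats::runif(n, 6, 48)
    dose_offset[category == "pre_drug"] <- stats::runif(sum(category == "pre_drug"), 96, 144)
    onset_delay <- runif_range(n, config$onset_delay_hours)
    peak <- runif_range(n, config$peak_fold)
    rise <- runif_range(n, config$rise_hours)
    pre_onset <- stats::runif(n, 12, 36) # pre-drug episode onset after admission

    los <- stats::rlnorm(n, log(12), 0.5) * exp(0.05 * true_aki)
    min_los <- (dose_offset + ifelse(true_aki, onset_delay + rise + 24, 24)) / 24 + 1
    los <- round(pmax(los, min_los), 2)
    cost <- round(stats::rlnorm(n, log(45000), 0.8) * exp(0.55 * true_aki), 2)
    discharge <- floor_minute(admission + los * 86400)
    los <- round(as.numeric(discharge - admission, units = "days"), 2)

    first_dose <- floor_minute(admission + dose_offset * 3600)
    last_dose <- floor_minute(pmin(first_dose + stats::runif(n, 72, 240) * 3600, discharge))

    baseline <- stats::rlnorm(
      n,
      log(config$baseline_scr_median) + log(1.14) * (sex == "male") +
        0.002 * pmax(age - 60, 0),
      config$baseline_scr_sdlog
    )

    scr_list <- vector("list", n)
    for (k in seq_len(n)) {
      span <- as.numeric(discharge[k] - admission[k], units = "hours")
      gaps <- stats::rexp(ceiling(span / config$sampling_gap_hours * 3 + 10),
        rate = 1 / config$sampling_gap_hours
      )
      t <- c(0, cumsum(gaps))
      t <- t[t <= span]
      # episode patients always get a draw at the episode peak, so every true
      # episode is represented in the recorded series
      if (true_aki[k]) {
        t <- sort(c(t, min(dose_offset[k] + onset_delay[k] + rise[k], span)))
      } else if (category[k] == "pre_drug") {
        t <- sort(c(t, pre_onset[k] + rise[k]))
      }
      s <- data.frame(time = t, value = rep(baseline[k], length(t)))
      if (true_aki[k]) {
        onset <- dose_offset[k] + onset_delay[k]
        s <- inject_aki_episode(s, onset, peak[k], rise[k])
      } else if (category[k] == "pre_drug") {
        s <- inject_aki_episode(s, pre_onset[k], peak[k], rise[k])
      }
      s$value <- s$value * exp(stats::rnorm(nrow(s), 0, config$noise_sigma))
      tt <- floor_minute(admission[k] + t * 3600)
      keep <- !duplicated(tt)
      scr_list[[k]] <- data.frame(
        patient_id = pid[k],
        time = tt[keep],
        value = round(s$value[keep], 1),
        stringsAsFactors = FALSE
      )
    }
    scr <- do.call(rbind, scr_list)
    rownames(scr) <- NULL

    aki_like <- true_aki | category != "standard" # shifts continuous labs
    covariates <- data.frame(patient_id = pid, as.data.frame(flags))
    covariates$baseline_scr <- round(baseline, 1)
    covariates$white_cell_count <- round(stats::rlnorm(n, log(8), 0.35) * exp(0.12 * aki_like), 2)
    covariates$red_cell_count <- round(stats::rlnorm(n, log(4.3), 0.13) * exp(-0.04 * aki_like), 2)
    covariates$platelet_count <- round(stats::rlnorm(n, log(200), 0.3) * exp(-0.05 * aki_like), 1)
    covariates$beta2_microglobulin <- round(stats::rlnorm(n, log(2.5), 0.4) * exp(0.2 * aki_like), 2)
    covariates$total_bilirubin <- round(stats::rlnorm(n, log(14), 0.5) * exp(0.1 * aki_like), 2)
    covariates$uric_acid <- round(stats::rlnorm(n, log(330), 0.3) * exp(0.08 * aki_like), 1)

    patients <- data.frame(
      patient_id = pid, sex = sex, age_years = age,
      age_group = age_group_of(age),
      admission_time = admission, discharge_time = discharge,
      aki_before_admission = category == "pre_admission",
      los_days = los, cost = cost, stringsAsFactors = FALSE
    )
    exposures <- data.frame(
      patient_id = pid, drug = config$drug,
      first_dose_time = first_dose, last_dose_time = last_dose,
      stringsAsFactors = FALSE
    )
    ground_truth <- data.frame(
      patient_id = pid, category = category, true_aki = true_aki,
      true_onset = ifelse(true_aki,
        format_timestamp(floor_minute(admission + (dose_offset + onset_delay) * 3600)),
        NA_character_
      ),
      linear_predictor = lp, stringsAsFactors = FALSE
    )

    cohort <- structure(
      list(
        patients = patients, creatinine = scr, exposures = exposures,
        covariates = covariates, drug = config$drug
      ),
      class = "aki_cohort"
    )
    list(cohort = cohort, ground_truth = ground_truth)
  })
}

#' Write a simulated cohort plus its ground truth to a directory
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_cohort(sim$cohort, dir)
  utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
    row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}
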
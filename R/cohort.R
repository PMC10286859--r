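# In-memory cohort representation and delimited-text I/O.
#
# A cohort is four tables keyed by patient_id:
#   patients   — demographics, admission interval, pre-admission AKI flag
#   creatinine — timestamped serum-creatinine, canonicalized to umol/L
#   exposures  — first/last administration of the drug under study
#   covariates — binary comorbidity/co-medication flags and continuous labs
# Timestamps are ISO 8601 at minute resolution, stored as POSIXct (UTC).

TIMESTAMP_FORMAT <- "%Y-%m-%dT%H:%M"

AGE_GROUPS <- c("youth", "middle_age", "old_age")

#' Age group from age in years
#'
#' Adults are grouped as youth (18-40), middle age (41-65) and old age (>= 66).
#'
#' @param age_years integer vector of ages, all >= 18.
#' @return factor with levels youth, middle_age, old_age.
#' @export
age_group_of <- function(age_years) {
  if (any(age_years < 18, na.rm = TRUE)) {
    stop_akiphen("age", "age_group_of is defined for adults (age >= 18) only")
  }
  cut(age_years,
    breaks = c(17, 40, 65, Inf),
    labels = AGE_GROUPS, right = TRUE
  )
}

parse_timestamp <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  as.POSIXct(x,
    tz = "UTC",
    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  )
}

format_timestamp <- function(x) format(x, TIMESTAMP_FORMAT, tz = "UTC")

parse_timestamp_col <- function(x, file, col) {
  out <- tryCatch(parse_timestamp(x), error = function(e) rep(NA, length(x)))
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) || anyNA(out)) {
    bad <- union(bad, which(is.na(out)))
    stop_akiphen(
      "timestamp",
      sprintf(
        "%s: unparseable timestamp in column '%s' at row(s) %s",
        file, col, paste(utils::head(bad, 10L), collapse = ", ")
      )
    )
  }
  out
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_akiphen(
      "missing_column",
      sprintf("%s: missing required column(s): %s", file, paste(missing, collapse = ", "))
    )
  }
}

#' Binary covariate flags and continuous laboratory columns
#'
#' Column names expected in `covariates.csv`: comorbidity, co-medication,
#' intervention and smoking flags (0/1) plus continuous labs.
#'
#' @name covariate_columns
#' @export
covariate_flags <- function() {
  c(
    "hypertension", "diabetes", "cerebral_apoplexy", "anemia",
    "coronary_heart_disease", "pneumonia", "shock", "sepsis", "heart_failure",
    "skin_tissue_infection", "neoplastic_disease", "gout",
    "chronic_renal_insufficiency", "pancreatitis", "copd", "hypokalemia",
    "hyponatremia", "cirrhosis", "hyperlipidemia",
    "nsaids", "arb", "acei", "ppi", "aminoglycoside", "diuretics",
    "crrt", "mechanical_ventilation", "smoking"
  )
}

#' @rdname covariate_columns
#' @export
covariate_labs <- function() {
  c(
    "baseline_scr", "white_cell_count", "red_cell_count", "platelet_count",
    "beta2_microglobulin", "total_bilirubin", "uric_acid"
  )
}

#' Load an inpatient cohort from delimited text files
#'
#' Reads `patients.csv`, `creatinine.csv`, `exposures.csv` and
#' `covariates.csv` from `dir`, validates the type invariants and returns an
#' `aki_cohort`. Creatinine is canonicalized to umol/L and sorted by time
#' within patient (ties in time broken by file order; tied-time duplicates
#' with equal values collapse to one measurement, differing values are an
#' error). Patients younger than 18 are dropped with a logged count.
#'
#' @param dir directory containing the four csv files.
#' @param drug drug under study; only exposures to this drug are kept.
#' @param lookback_days how far before admission a creatinine measurement may
#'   fall and still be retained (default 7 days).
#' @return an object of class `aki_cohort`: a list with elements `patients`,
#'   `creatinine`, `exposures`, `covariates` (data frames) and `drug`.
#' @export
load_cohort <- function(dir, drug = "cefoperazone_sulbactam", lookback_days = 7) {
  paths <- file.path(dir, c("patients.csv", "creatinine.csv", "exposures.csv", "covariates.csv"))
  for (p in paths) {
    if (!file.exists(p)) stop_akiphen("missing_file", sprintf("cohort file not found: %s", p))
  }

  pat <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  require_columns(pat, c(
    "patient_id", "sex", "age_years", "admission_time", "discharge_time",
    "aki_before_admission", "los_days", "cost"
  ), "patients.csv")
  pat$patient_id <- as.character(pat$patient_id)
  if (anyDuplicated(pat$patient_id)) {
    stop_akiphen("duplicate_patient", sprintf(
      "patients.csv: duplicated patient_id(s): %s",
      paste(unique(pat$patient_id[duplicated(pat$patient_id)]), collapse = ", ")
    ))
  }
  if (!all(pat$sex %in% c("male", "female"))) {
    bad <- which(!pat$sex %in% c("male", "female"))
    stop_akiphen("sex", sprintf("patients.csv: invalid sex at row(s) %s", paste(bad, collapse = ", ")))
  }
  pat$admission_time <- parse_timestamp_col(pat$admission_time, "patients.csv", "admission_time")
  pat$discharge_time <- parse_timestamp_col(pat$discharge_time, "patients.csv", "discharge_time")
  bad <- which(pat$admission_time >= pat$discharge_time)
  if (length(bad)) {
    stop_akiphen("interval", sprintf(
      "patients.csv: admission_time >= discharge_time for patient(s) %s (row %s)",
      paste(pat$patient_id[bad], collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  pat$aki_before_admission <- as.logical(pat$aki_before_admission)
  if (anyNA(pat$aki_before_admission)) {
    stop_akiphen("flag", "patients.csv: aki_before_admission must be TRUE/FALSE (or 0/1)")
  }
  if (any(pat$los_days < 0) || any(pat$cost < 0)) {
    stop_akiphen("negative", "patients.csv: los_days and cost must be nonnegative")
  }
  minors <- pat$age_years < 18
  if (any(minors)) {
    message(sprintf("load_cohort: dropped %d patient(s) younger than 18", sum(minors)))
    pat <- pat[!minors, , drop = FALSE]
  }
  pat$age_group <- age_group_of(pat$age_years)
  pat <- pat[, c(
    "patient_id", "sex", "age_years", "age_group", "admission_time",
    "discharge_time", "aki_before_admission", "los_days", "cost"
  )]

  scr <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  require_columns(scr, c("patient_id", "time", "value", "unit"), "creatinine.csv")
  scr$patient_id <- as.character(scr$patient_id)
  scr$time <- parse_timestamp_col(scr$time, "creatinine.csv", "time")
  if (any(!scr$unit %in% SCR_UNITS)) {
    bad <- which(!scr$unit %in% SCR_UNITS)
    stop_akiphen("unknown_unit", sprintf(
      "creatinine.csv: unknown unit '%s' at row(s) %s",
      paste(unique(scr$unit[bad]), collapse = ", "), paste(utils::head(bad, 10L), collapse = ", ")
    ))
  }
  if (any(scr$value <= 0 | !is.finite(scr$value))) {
    bad <- which(scr$value <= 0 | !is.finite(scr$value))
    stop_akiphen("invalid_value", sprintf(
      "creatinine.csv: nonpositive value at row(s) %s", paste(utils::head(bad, 10L), collapse = ", ")
    ))
  }
  mgdl <- scr$unit == "mg_per_dL"
  scr$value[mgdl] <- convert_creatinine(scr$value[mgdl], "mg_per_dL", "umol_per_L")
  scr$unit <- NULL
  scr <- scr[scr$patient_id %in% pat$patient_id, , drop = FALSE]

  # stable sort keeps file order within tied timestamps
  ord <- order(match(scr$patient_id, pat$patient_id), scr$time)
  scr <- scr[ord, , drop = FALSE]
  key <- paste(scr$patient_id, format_timestamp(scr$time))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    differs <- abs(scr$value[dup] - scr$value[first]) > 1e-9
    if (any(differs)) {
      stop_akiphen("duplicate_measurement", sprintf(
        "creatinine.csv: duplicate (patient, time) with differing values for patient(s) %s",
        paste(unique(scr$patient_id[dup][differs]), collapse = ", ")
      ))
    }
    scr <- scr[!dup, , drop = FALSE]
  }
  adm <- pat$admission_time[match(scr$patient_id, pat$patient_id)]
  dis <- pat$discharge_time[match(scr$patient_id, pat$patient_id)]
  out_of_window <- scr$time < adm - lookback_days * 86400 | scr$time > dis
  if (any(out_of_window)) {
    stop_akiphen("measurement_window", sprintf(
      "creatinine.csv: %d measurement(s) outside [admission - %g d, discharge] for patient(s) %s",
      sum(out_of_window), lookback_days,
      paste(unique(scr$patient_id[out_of_window]), collapse = ", ")
    ))
  }
  rownames(scr) <- NULL

  exp_ <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  require_columns(exp_, c("patient_id", "drug", "first_dose_time", "last_dose_time"), "exposures.csv")
  exp_$patient_id <- as.character(exp_$patient_id)
  exp_$first_dose_time <- parse_timestamp_col(exp_$first_dose_time, "exposures.csv", "first_dose_time")
  exp_$last_dose_time <- parse_timestamp_col(exp_$last_dose_time, "exposures.csv", "last_dose_time")
  if (any(exp_$first_dose_time > exp_$last_dose_time)) {
    bad <- which(exp_$first_dose_time > exp_$last_dose_time)
    stop_akiphen("interval", sprintf(
      "exposures.csv: first_dose_time > last_dose_time at row(s) %s", paste(bad, collapse = ", ")
    ))
  }
  exp_ <- exp_[exp_$drug == drug & exp_$patient_id %in% pat$patient_id, , drop = FALSE]
  if (anyDuplicated(exp_$patient_id)) {
    stop_akiphen("duplicate_exposure", sprintf(
      "exposures.csv: more than one '%s' exposure for patient(s) %s",
      drug, paste(unique(exp_$patient_id[duplicated(exp_$patient_id)]), collapse = ", ")
    ))
  }
  adm <- pat$admission_time[match(exp_$patient_id, pat$patient_id)]
  dis <- pat$discharge_time[match(exp_$patient_id, pat$patient_id)]
  bad <- which(exp_$first_dose_time < adm | exp_$first_dose_time > dis)
  if (length(bad)) {
    stop_akiphen("exposure", sprintf(
      "exposures.csv: first_dose_time outside admission interval for patient(s) %s",
      paste(exp_$patient_id[bad], collapse = ", ")
    ))
  }
  rownames(exp_) <- NULL

  cov <- utils::read.csv(paths[4], stringsAsFactors = FALSE)
  require_columns(cov, "patient_id", "covariates.csv")
  cov$patient_id <- as.character(cov$patient_id)
  cov <- cov[cov$patient_id %in% pat$patient_id, , drop = FALSE]
  for (fl in intersect(covariate_flags(), names(cov))) {
    v <- cov[[fl]]
    if (is.logical(v)) v <- as.integer(v)
    if (anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop_akiphen("flag", sprintf("covariates.csv: column '%s' must be 0/1 with no missing values", fl))
    }
    cov[[fl]] <- as.integer(v)
  }
  for (lb in intersect(covariate_labs(), names(cov))) {
    v <- cov[[lb]]
    if (any(!is.na(v) & v <= 0)) {
      stop_akiphen("invalid_value", sprintf("covariates.csv: column '%s' must be positive when present", lb))
    }
  }
  rownames(cov) <- NULL

  structure(
    list(patients = pat, creatinine = scr, exposures = exp_, covariates = cov, drug = drug),
    class = "aki_cohort"
  )
}

#' Write a cohort back to delimited text files
#'
#' Inverse of [load_cohort()]: writes the four csv files in canonical form
#' (creatinine in umol/L, timestamps at minute resolution), so that
#' `load_cohort(write_cohort(x))` reproduces `x` field for field.
#'
#' @param cohort an `aki_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aki_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- cohort$patients
  pat$admission_time <- format_timestamp(pat$admission_time)
  pat$discharge_time <- format_timestamp(pat$discharge_time)
  pat$age_group <- NULL
  utils::write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE, quote = FALSE)
  scr <- cohort$creatinine
  scr$time <- format_timestamp(scr$time)
  scr$unit <- "umol_per_L"
  utils::write.csv(scr, file.path(dir, "creatinine.csv"), row.names = FALSE, quote = FALSE)
  exp_ <- cohort$exposures
  exp_$first_dose_time <- format_timestamp(exp_$first_dose_time)
  exp_$last_dose_time <- format_timestamp(exp_$last_dose_time)
  utils::write.csv(exp_, file.path(dir, "exposures.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf(
    "aki_cohort: %d patients, %d creatinine measurements, drug = %s\n",
    nrow(x$patients), nrow(x$creatinine), x$drug
  ))
  invisible(x)
}

# One patient's canonical creatinine series as a data.frame(time, value),
# time-sorted, umol/L.
patient_series <- function(cohort, patient_id) {
  s <- cohort$creatinine[cohort$creatinine$patient_id == patient_id, c("time", "value")]
  rownames(s) <- NULL
  s
}
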
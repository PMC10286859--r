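# Fixtures built in code. Times are numeric hours unless a POSIXct cohort is
# needed; the detector accepts either.

mk_series <- function(time, value) data.frame(time = time, value = value)

mk_patient <- function(id = "P1", admission = 0, discharge = 500, flag = FALSE) {
  list(
    patient_id = id, admission_time = admission, discharge_time = discharge,
    aki_before_admission = flag
  )
}

mk_exposure <- function(first_dose = 100, last_dose = first_dose + 72) {
  list(first_dose_time = first_dose, last_dose_time = last_dose)
}

# Random adjudication scenario for property tests: wide multiplicative noise
# so absolute and ratio hits, pre-dose hits and misses all occur.
random_case <- function(n_points = sample(0:20, 1)) {
  span <- 400
  t <- sort(round(runif(n_points, 0, span), 3))
  t <- t[!duplicated(t)]
  baseline <- runif(1, 40, 130)
  sigma <- runif(1, 0.05, 0.35)
  v <- baseline * exp(rnorm(length(t), 0, sigma))
  list(
    patient = mk_patient(flag = runif(1) < 0.05, discharge = span),
    exposure = mk_exposure(first_dose = runif(1, 0, span * 0.75)),
    series = mk_series(t, v)
  )
}

same_adjudication <- function(a, b) {
  if (a$status != b$status) return(FALSE)
  if (is.null(a$onset) != is.null(b$onset)) return(FALSE)
  if (!is.null(a$onset)) {
    o <- a$onset
    p <- b$onset
    if (o$criterion != p$criterion) return(FALSE)
    if (!isTRUE(all.equal(
      c(o$earlier_time, o$later_time, o$earlier_value, o$later_value),
      c(p$earlier_time, p$later_time, p$earlier_value, p$later_value)
    ))) {
      return(FALSE)
    }
  }
  TRUE
}

# A small cohort on disk for I/O tests.
write_toy_cohort <- function(dir, patients, creatinine, exposures, covariates) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(patients, file.path(dir, "patients.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(creatinine, file.path(dir, "creatinine.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(exposures, file.path(dir, "exposures.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(covariates, file.path(dir, "covariates.csv"), row.names = FALSE, quote = FALSE)
  dir
}

toy_tables <- function() {
  list(
    patients = data.frame(
      patient_id = c("A", "B", "C"),
      sex = c("male", "female", "male"),
      age_years = c(70, 45, 30),
      admission_time = c("2018-03-01T08:00", "2018-04-02T10:30", "2018-05-03T12:00"),
      discharge_time = c("2018-03-15T08:00", "2018-04-20T10:30", "2018-05-10T12:00"),
      aki_before_admission = c(FALSE, FALSE, FALSE),
      los_days = c(14, 18, 7),
      cost = c(50000, 62000, 30000)
    ),
    creatinine = data.frame(
      patient_id = c("A", "A", "A", "B", "B", "C"),
      time = c(
        "2018-03-01T09:00", "2018-03-03T09:00", "2018-03-04T09:00",
        "2018-04-02T11:00", "2018-04-05T11:00", "2018-05-03T13:00"
      ),
      value = c(60, 62, 95, 1.0, 1.1, 70),
      unit = c(rep("umol_per_L", 3), "mg_per_dL", "mg_per_dL", "umol_per_L")
    ),
    exposures = data.frame(
      patient_id = c("A", "B", "C"),
      drug = "cefoperazone_sulbactam",
      first_dose_time = c("2018-03-02T08:00", "2018-04-03T10:00", "2018-05-04T09:00"),
      last_dose_time = c("2018-03-09T08:00", "2018-04-10T10:00", "2018-05-08T09:00")
    ),
    covariates = data.frame(
      patient_id = c("A", "B", "C"),
      hypertension = c(1, 0, 0),
      diuretics = c(1, 1, 0),
      baseline_scr = c(60, 88, 70)
    )
  )
}
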
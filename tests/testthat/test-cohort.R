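test_that("a small fixture loads with sorted, unit-canonical series", {
  tabs <- toy_tables()
  dir <- write_toy_cohort(withr::local_tempdir(), tabs$patients, tabs$creatinine, tabs$exposures, tabs$covariates)
  ch <- load_cohort(dir)
  expect_s3_class(ch, "aki_cohort")
  expect_equal(nrow(ch$patients), 3)
  expect_equal(ch$patients$age_group, factor(c("old_age", "middle_age", "youth"),
    levels = c("youth", "middle_age", "old_age")
  ))
  # mg/dL rows canonicalized
  b <- ch$creatinine[ch$creatinine$patient_id == "B", ]
  expect_equal(b$value, c(88.4, 97.24))
  # per-patient times nondecreasing
  expect_true(all(tapply(
    as.numeric(ch$creatinine$time), ch$creatinine$patient_id,
    function(t) all(diff(t) >= 0)
  )))
})

test_that("invariant violations are rejected with identifying diagnostics", {
  tabs <- toy_tables()
  bad <- tabs$patients
  bad$discharge_time[2] <- "2018-04-01T00:00" # before admission
  dir <- write_toy_cohort(withr::local_tempdir(), bad, tabs$creatinine, tabs$exposures, tabs$covariates)
  expect_error(load_cohort(dir), "B", class = "akiphen_interval_error")

  scr <- rbind(tabs$creatinine, data.frame(
    patient_id = "A", time = "2018-03-03T09:00", value = 80, unit = "umol_per_L"
  ))
  dir <- write_toy_cohort(withr::local_tempdir(), tabs$patients, scr, tabs$exposures, tabs$covariates)
  expect_error(load_cohort(dir), "A", class = "akiphen_duplicate_measurement_error")

  dir <- write_toy_cohort(
    withr::local_tempdir(), tabs$patients,
    tabs$creatinine[, c("patient_id", "time", "value")], tabs$exposures, tabs$covariates
  )
  expect_error(load_cohort(dir), "unit", class = "akiphen_missing_column_error")
})

test_that("tied-time duplicates with equal values collapse to one row", {
  tabs <- toy_tables()
  scr <- rbind(tabs$creatinine, data.frame(
    patient_id = "A", time = "2018-03-03T09:00", value = 62, unit = "umol_per_L"
  ))
  dir <- write_toy_cohort(withr::local_tempdir(), tabs$patients, scr, tabs$exposures, tabs$covariates)
  ch <- load_cohort(dir)
  expect_equal(sum(ch$creatinine$patient_id == "A"), 3)
})

test_that("patients younger than 18 are dropped with a logged count", {
  tabs <- toy_tables()
  tabs$patients$age_years[3] <- 15
  dir <- write_toy_cohort(withr::local_tempdir(), tabs$patients, tabs$creatinine, tabs$exposures, tabs$covariates)
  expect_message(ch <- load_cohort(dir), "1 patient")
  expect_equal(ch$patients$patient_id, c("A", "B"))
  expect_false("C" %in% ch$exposures$patient_id)
})

test_that("write/load round-trip reproduces a simulated cohort field for field", {
  sim <- simulate_cohort(simulation_config(n_patients = 40, rng_seed = 11))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  back <- load_cohort(dir, drug = sim$cohort$drug)
  expect_equal(back$patients, sim$cohort$patients)
  expect_equal(back$creatinine, sim$cohort$creatinine)
  expect_equal(back$exposures, sim$cohort$exposures)
  expect_equal(back$covariates, sim$cohort$covariates)
})

test_that("mixed-unit input yields the same adjudication as all-umol input", {
  sim <- simulate_cohort(simulation_config(n_patients = 30, rng_seed = 5))
  dir1 <- withr::local_tempdir()
  write_cohort(sim$cohort, dir1)
  # rewrite half the creatinine rows in mg/dL
  scr <- utils::read.csv(file.path(dir1, "creatinine.csv"))
  half <- seq_len(nrow(scr)) %% 2 == 0
  scr$value[half] <- scr$value[half] / 88.4
  scr$unit[half] <- "mg_per_dL"
  utils::write.csv(scr, file.path(dir1, "creatinine.csv"), row.names = FALSE, quote = FALSE)
  mixed <- load_cohort(dir1, drug = sim$cohort$drug)
  expect_equal(
    adjudicate_cohort(mixed)$status,
    adjudicate_cohort(sim$cohort)$status
  )
})

test_that("age grouping follows the 18-40 / 41-65 / >=66 cut-points", {
  expect_equal(
    as.character(age_group_of(c(18, 40, 41, 65, 66, 90))),
    c("youth", "youth", "middle_age", "middle_age", "old_age", "old_age")
  )
  expect_error(age_group_of(17), class = "akiphen_age_error")
})
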
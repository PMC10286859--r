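test_that("absolute criterion fires at and above the 26.5 umol/L threshold", {
  th <- detection_thresholds()
  ev <- find_absolute_rise(mk_series(c(0, 24), c(60, 90)), th, from_time = 0)
  expect_equal(ev$criterion, "absolute_48h")
  expect_equal(
    c(ev$earlier_time, ev$later_time, ev$earlier_value, ev$later_value),
    c(0, 24, 60, 90)
  )
  expect_null(find_absolute_rise(mk_series(c(0, 24), c(60, 86.4)), th))
  expect_false(is.null(find_absolute_rise(mk_series(c(0, 24), c(60, 86.5)), th)))
  # outside the 48-h window
  expect_null(find_absolute_rise(mk_series(c(0, 49), c(60, 95)), th))
  # decreases never trigger
  expect_null(find_absolute_rise(mk_series(c(0, 24), c(90, 60)), th))
})

test_that("ratio criterion is inclusive at 1.5 within the 7-day window", {
  th <- detection_thresholds()
  ev <- find_ratio_rise(mk_series(c(0, 6 * 24), c(60, 90)), th)
  expect_equal(ev$criterion, "ratio_7d")
  expect_null(find_ratio_rise(mk_series(c(0, 8 * 24), c(60, 120)), th))
  # boundary: gap exactly 7 days counts
  expect_false(is.null(find_ratio_rise(mk_series(c(0, 7 * 24), c(60, 90)), th)))
})

test_that("empty and singleton series yield no event", {
  th <- detection_thresholds()
  expect_null(find_absolute_rise(mk_series(numeric(0), numeric(0)), th))
  expect_null(find_ratio_rise(mk_series(10, 80), th))
})

test_that("earliest pair selection prefers smallest later time, then largest rise", {
  th <- detection_thresholds()
  # two qualifying later points; the earlier one must be chosen
  ev <- find_absolute_rise(mk_series(c(0, 10, 20), c(60, 90, 130)), th)
  expect_equal(ev$later_time, 10)
  # one later point, two qualifying partners: largest rise wins
  ev <- find_absolute_rise(mk_series(c(0, 5, 24), c(60, 50, 95)), th)
  expect_equal(ev$earlier_value, 50)
  # equal rises: earliest partner wins
  ev <- find_absolute_rise(mk_series(c(0, 5, 24), c(60, 60, 95)), th)
  expect_equal(ev$earlier_time, 0)
})

test_that("adjudication applies baseline anchoring and exclusion rules", {
  # post-dose absolute rise from the baseline at dose time
  a <- adjudicate(
    mk_patient(), mk_exposure(first_dose = 100),
    mk_series(c(100, 112), c(60, 95))
  )
  expect_equal(a$status, "AKI_POST_DRUG")
  expect_equal(a$onset$criterion, "absolute_48h")
  expect_equal(a$baseline_value, 60)
  expect_equal(a$baseline_time, 100)

  # pre-dose rise attributes AKI to other causes regardless of post-dose data
  b <- adjudicate(
    mk_patient(), mk_exposure(first_dose = 100),
    mk_series(c(0, 24, 120), c(60, 100, 60))
  )
  expect_equal(b$status, "EXCLUDED_PRE_DRUG_AKI")
  expect_null(b$onset)

  # pre-admission flag wins over everything
  c_ <- adjudicate(
    mk_patient(flag = TRUE), mk_exposure(first_dose = 100),
    mk_series(c(100, 112), c(60, 95))
  )
  expect_equal(c_$status, "EXCLUDED_PRE_ADMISSION")

  # no baseline before the dose -> unassessable
  d <- adjudicate(
    mk_patient(), mk_exposure(first_dose = 50),
    mk_series(c(60, 80), c(60, 64))
  )
  expect_equal(d$status, "UNASSESSABLE")

  # baseline but no post-dose measurement -> unassessable
  e <- adjudicate(
    mk_patient(), mk_exposure(first_dose = 100),
    mk_series(c(0, 50), c(60, 64))
  )
  expect_equal(e$status, "UNASSESSABLE")

  # constant series with baseline and post-dose data -> no AKI
  f <- adjudicate(
    mk_patient(), mk_exposure(first_dose = 100),
    mk_series(seq(0, 400, by = 24), rep(70, 17))
  )
  expect_equal(f$status, "NO_AKI")

  expect_error(
    adjudicate(mk_patient(discharge = 50), mk_exposure(first_dose = 100), mk_series(0, 60)),
    class = "akiphen_exposure_error"
  )
})

test_that("intermediate pre-dose values are not comparators for post-dose rises", {
  # the early 60 would qualify against the post value (90/60 = 1.5), but the
  # baseline is the most recent pre-dose measurement (80): no qualifying rise
  a <- adjudicate(
    mk_patient(), mk_exposure(first_dose = 100),
    mk_series(c(10, 90, 130), c(60, 80, 90))
  )
  expect_equal(a$status, "NO_AKI")
  expect_equal(a$baseline_value, 80)
})

test_that("fast adjudication matches the exhaustive pair-scan oracle", {
  set.seed(42)
  for (rep in 1:300) {
    cs <- random_case()
    fast <- adjudicate(cs$patient, cs$exposure, cs$series)
    slow <- brute_force_adjudicate(cs$patient, cs$exposure, cs$series)
    expect_true(same_adjudication(fast, slow))
  }
})

test_that("every patient gets exactly one status and onset iff AKI", {
  set.seed(7)
  for (rep in 1:100) {
    cs <- random_case()
    a <- adjudicate(cs$patient, cs$exposure, cs$series)
    expect_true(a$status %in% c(
      "AKI_POST_DRUG", "NO_AKI", "EXCLUDED_PRE_ADMISSION",
      "EXCLUDED_PRE_DRUG_AKI", "UNASSESSABLE"
    ))
    expect_identical(!is.null(a$onset), a$status == "AKI_POST_DRUG")
    if (!is.null(a$onset)) {
      expect_gte(a$onset$later_time, cs$exposure$first_dose_time)
      expect_lt(a$onset$earlier_time, a$onset$later_time)
    }
  }
})

test_that("incidence counts only analyzable patients", {
  st <- c("AKI_POST_DRUG", "NO_AKI", "NO_AKI", "EXCLUDED_PRE_ADMISSION")
  inc <- cohort_incidence(st)
  expect_equal(inc$n_aki, 1)
  expect_equal(inc$n_analyzable, 3)
  expect_equal(inc$proportion, 1 / 3)
  expect_equal(cohort_incidence(rep("NO_AKI", 5))$proportion, 0)
  expect_error(
    cohort_incidence(rep("EXCLUDED_PRE_ADMISSION", 3)),
    class = "akiphen_no_analyzable_error"
  )
  expect_error(cohort_incidence(character(0)), class = "akiphen_empty_error")
})

test_that("planted post-dose AKI is recovered at its true rate under dense sampling", {
  cfg <- simulation_config(
    n_patients = 600, rng_seed = 21, sampling_gap_hours = 6,
    beta_true = c(diuretics = 0), target_incidence = 0.10,
    frac_pre_admission = 0, frac_pre_drug = 0
  )
  sim <- simulate_cohort(cfg)
  adj <- adjudicate_cohort(sim$cohort)
  inc <- cohort_incidence(adj)
  true_rate <- mean(sim$ground_truth$true_aki)
  se <- sqrt(0.1 * 0.9 / inc$n_analyzable)
  expect_lt(abs(inc$proportion - true_rate), 3 * se + 0.02) # small FP allowance
})
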
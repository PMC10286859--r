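test_that("generation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_patients = 120, rng_seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_cohort(cfg), d1)
  write_simulation(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      label = f
    )
  }
})

test_that("a pure-intercept model hits the target marginal incidence", {
  cfg <- simulation_config(
    n_patients = 2000, rng_seed = 17,
    beta_true = c(diuretics = 0), target_incidence = 0.10,
    frac_pre_admission = 0, frac_pre_drug = 0
  )
  sim <- simulate_cohort(cfg)
  rate <- mean(sim$ground_truth$true_aki)
  expect_lt(abs(rate - 0.10), 3 * sqrt(0.10 * 0.90 / 2000))
})

test_that("an unreachable target incidence reports the achievable range", {
  expect_error(
    simulate_cohort(simulation_config(
      n_patients = 50, rng_seed = 1, target_incidence = 1e-18
    )),
    "achievable",
    class = "akiphen_incidence_unreachable_error"
  )
})

test_that("episode injection follows the linear-rise-then-plateau envelope", {
  s <- mk_series(seq(0, 96, by = 6), rep(60, 17))
  out <- inject_aki_episode(s, onset = 24, peak_fold = 2, rise_hours = 24)
  expect_equal(out$value[s$time <= 24], rep(60, 5)) # pre-onset untouched
  expect_equal(out$value[s$time == 36], 90) # halfway up
  expect_equal(out$value[s$time >= 48], rep(120, 9)) # plateau at 2x

  expect_equal(inject_aki_episode(s, 24, 1.0, 24), s) # identity at fold 1

  expect_warning(
    unchanged <- inject_aki_episode(s, onset = 200, peak_fold = 2, rise_hours = 24),
    class = "akiphen_episode_after_series_warning"
  )
  expect_equal(unchanged, s)
})

test_that("episode magnitude determines which criterion can fire", {
  pat <- mk_patient(discharge = 240)
  exp_ <- mk_exposure(first_dose = 24)
  flat <- mk_series(seq(0, 240, by = 6), rep(50, 41))
  bumped <- inject_aki_episode(flat, 48, 1.55, 24)
  expect_false(is.null(find_ratio_rise(bumped, from_time = 24))) # 1.55 >= 1.5
  fires <- adjudicate(pat, exp_, bumped)
  expect_equal(fires$status, "AKI_POST_DRUG")
  quiet <- adjudicate(pat, exp_, inject_aki_episode(flat, 48, 1.4, 24))
  expect_equal(quiet$status, "NO_AKI") # rise 20 < 26.5 and ratio 1.4 < 1.5
})

test_that("detector recovers planted episodes under dense sampling", {
  cfg <- simulation_config(
    n_patients = 800, rng_seed = 23, sampling_gap_hours = 6
  )
  sim <- simulate_cohort(cfg)
  adj <- adjudicate_cohort(sim$cohort)
  m <- merge(adj, sim$ground_truth, by = "patient_id")
  std <- m$category == "standard"
  base <- sim$cohort$covariates$baseline_scr[match(m$patient_id, sim$cohort$covariates$patient_id)]
  sens <- mean(m$status[std & m$true_aki] == "AKI_POST_DRUG")
  expect_gte(sens, 0.95)
  # with 5% multiplicative noise the fixed 26.5 umol/L absolute criterion has
  # a nonzero noise-driven false-positive rate on high-baseline patients (a
  # rise of 26.5 is only ~2.3 noise SDs when baseline exceeds ~100 umol/L);
  # below that baseline false positives are rare
  fpr_low <- mean(m$status[std & !m$true_aki & base < 100] == "AKI_POST_DRUG")
  fpr_all <- mean(m$status[std & !m$true_aki] == "AKI_POST_DRUG")
  expect_lte(fpr_low, 0.02)
  expect_lte(fpr_all, 0.035)
})

test_that("generated exclusion cases are adjudicated to their statuses", {
  cfg <- simulation_config(
    n_patients = 1000, rng_seed = 29, sampling_gap_hours = 6,
    frac_pre_admission = 0.05, frac_pre_drug = 0.05
  )
  sim <- simulate_cohort(cfg)
  adj <- adjudicate_cohort(sim$cohort)
  m <- merge(adj, sim$ground_truth, by = "patient_id")
  pre_adm <- m$category == "pre_admission"
  pre_drug <- m$category == "pre_drug"
  expect_gte(sum(pre_adm), 20)
  expect_gte(sum(pre_drug), 20)
  expect_equal(mean(m$status[pre_adm] == "EXCLUDED_PRE_ADMISSION"), 1)
  expect_gte(mean(m$status[pre_drug] == "EXCLUDED_PRE_DRUG_AKI"), 0.98)
})

test_that("true AKI episodes imply an injected rise in the written series", {
  sim <- simulate_cohort(simulation_config(n_patients = 100, rng_seed = 41))
  gt <- sim$ground_truth
  scr <- sim$cohort$creatinine
  for (pid in gt$patient_id[gt$true_aki][1:10]) {
    s <- scr[scr$patient_id == pid, ]
    expect_gt(max(s$value) / min(s$value), 1.4)
  }
})
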
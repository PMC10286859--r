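# Drug-anchored KDIGO creatinine adjudication.
#
# A patient has AKI after the drug if, among the baseline measurement (most
# recent at or before the first dose) and all later in-admission measurements,
# some later value rises >= 26.5 umol/L above any earlier value within 48 h,
# or reaches >= 1.5 times any earlier value within 7 days. Both comparisons
# are inclusive and consider every ordered pair inside the window, not just
# adjacent pairs. Episodes that complete before the first dose are attributed
# to other causes and excluded, as are patients flagged with AKI before
# admission. Rises only: decreases never trigger either criterion.

AKI_STATUSES <- c(
  "AKI_POST_DRUG", "NO_AKI", "EXCLUDED_PRE_ADMISSION",
  "EXCLUDED_PRE_DRUG_AKI", "UNASSESSABLE"
)

#' KDIGO creatinine detection thresholds
#'
#' @param delta_abs absolute rise threshold in umol/L (default 26.5).
#' @param window_abs_hours window for the absolute criterion (default 48 h).
#' @param ratio fold-rise threshold (default 1.5).
#' @param window_ratio_hours window for the ratio criterion (default 7 days).
#' @return a `detection_thresholds` list. Both comparisons are inclusive (>=).
#' @export
detection_thresholds <- function(delta_abs = 26.5, window_abs_hours = 48,
                                 ratio = 1.5, window_ratio_hours = 7 * 24) {
  stopifnot(
    delta_abs > 0, window_abs_hours > 0,
    ratio > 0, window_ratio_hours > 0
  )
  structure(
    list(
      delta_abs = delta_abs, window_abs_hours = window_abs_hours,
      ratio = ratio, window_ratio_hours = window_ratio_hours
    ),
    class = "detection_thresholds"
  )
}

# Shared pair scan. times numeric (hours) or POSIXct; returns the earliest
# qualifying event: minimal later time t_j >= from_time with some earlier
# t_i, t_j - t_i <= window and rise(v_i, v_j) >= threshold. Among earlier
# partners of the chosen t_j the largest rise wins, then the smallest t_i.
scan_pairs <- function(time, value, from_time, window_hours, threshold, type) {
  n <- length(time)
  if (n < 2L) return(NULL)
  th <- as_hours(time)
  from <- as_hours(from_time)
  for (j in 2:n) {
    if (th[j] < from) next
    i <- which(th < th[j] & th[j] - th <= window_hours)
    if (!length(i)) next
    rise <- if (type == "absolute_48h") value[j] - value[i] else value[j] / value[i]
    ok <- rise >= threshold
    if (any(ok)) {
      i <- i[ok]
      rise <- rise[ok]
      best <- i[order(-rise, th[i])][1L]
      return(onset_event(time[best], time[j], value[best], value[j], type))
    }
  }
  NULL
}

as_hours <- function(x) {
  if (inherits(x, "POSIXct")) as.numeric(x) / 3600 else as.numeric(x)
}

onset_event <- function(earlier_time, later_time, earlier_value, later_value, criterion) {
  structure(
    list(
      earlier_time = earlier_time, later_time = later_time,
      earlier_value = earlier_value, later_value = later_value,
      criterion = criterion
    ),
    class = "onset_event"
  )
}

#' Find the earliest qualifying creatinine rise
#'
#' `find_absolute_rise()` scans for a later value exceeding any earlier value
#' by at least `delta_abs` umol/L within the 48-hour window;
#' `find_ratio_rise()` scans for a later value at least `ratio` times any
#' earlier value within the 7-day window. Both return the event with the
#' smallest later-measurement time not before `from_time` (ties among earlier
#' partners broken by largest rise, then earliest partner), or `NULL` when no
#' pair qualifies.
#'
#' @param series data.frame with columns `time` (POSIXct or numeric hours,
#'   ascending) and `value` (umol/L).
#' @param thresholds a [detection_thresholds()] object.
#' @param from_time earliest admissible later-measurement time.
#' @return an `onset_event` (earlier/later time and value, criterion) or `NULL`.
#' @export
find_absolute_rise <- function(series, thresholds = detection_thresholds(),
                               from_time = -Inf) {
  scan_pairs(
    series$time, series$value, from_time,
    thresholds$window_abs_hours, thresholds$delta_abs, "absolute_48h"
  )
}

#' @rdname find_absolute_rise
#' @export
find_ratio_rise <- function(series, thresholds = detection_thresholds(),
                            from_time = -Inf) {
  scan_pairs(
    series$time, series$value, from_time,
    thresholds$window_ratio_hours, thresholds$ratio, "ratio_7d"
  )
}

# Earliest of two optional events; the absolute criterion wins an exact tie
# on later-measurement time.
earliest_event <- function(abs_event, ratio_event) {
  if (is.null(abs_event)) return(ratio_event)
  if (is.null(ratio_event)) return(abs_event)
  if (as_hours(ratio_event$later_time) < as_hours(abs_event$later_time)) ratio_event else abs_event
}

#' Adjudicate one patient's AKI status relative to a drug exposure
#'
#' Applies the exclusion rules and both KDIGO creatinine criteria anchored at
#' the first dose:
#' \enumerate{
#'   \item a pre-admission AKI flag excludes the patient
#'     (`EXCLUDED_PRE_ADMISSION`);
#'   \item either criterion firing on the measurements in
#'     \eqn{[admission, first~dose)} excludes the patient as AKI from other
#'     causes (`EXCLUDED_PRE_DRUG_AKI`);
#'   \item otherwise the baseline is the most recent measurement at or before
#'     the first dose, and either criterion firing on baseline + post-dose
#'     measurements yields `AKI_POST_DRUG` with the earliest onset event
#'     across both criteria;
#'   \item else `NO_AKI` when a baseline and at least one post-dose
#'     measurement exist, `UNASSESSABLE` otherwise.
#' }
#'
#' @param patient one row of a cohort's `patients` table (list or data.frame
#'   row with `admission_time`, `discharge_time`, `aki_before_admission`).
#' @param exposure matching row of `exposures` (with `first_dose_time`).
#' @param series the patient's canonical creatinine series (`time`, `value`).
#' @param thresholds a [detection_thresholds()] object.
#' @return an `aki_adjudication`: `patient_id`, `status`, `onset` (an
#'   `onset_event`, present iff `AKI_POST_DRUG`), `baseline_value`,
#'   `baseline_time`.
#' @export
adjudicate <- function(patient, exposure, series,
                       thresholds = detection_thresholds()) {
  adm <- patient$admission_time
  dis <- patient$discharge_time
  dose <- exposure$first_dose_time
  if (as_hours(dose) < as_hours(adm) || as_hours(dose) > as_hours(dis)) {
    stop_akiphen("exposure", sprintf(
      "first_dose_time outside admission interval for patient %s", patient$patient_id
    ))
  }
  result <- function(status, onset = NULL, baseline_value = NULL, baseline_time = NULL) {
    structure(
      list(
        patient_id = patient$patient_id, status = status, onset = onset,
        baseline_value = baseline_value, baseline_time = baseline_time
      ),
      class = "aki_adjudication"
    )
  }

  if (isTRUE(patient$aki_before_admission)) {
    return(result("EXCLUDED_PRE_ADMISSION"))
  }

  t <- as_hours(series$time)
  pre <- series[t >= as_hours(adm) & t < as_hours(dose), , drop = FALSE]
  pre_hit <- earliest_event(
    find_absolute_rise(pre, thresholds, from_time = adm),
    find_ratio_rise(pre, thresholds, from_time = adm)
  )
  if (!is.null(pre_hit)) {
    return(result("EXCLUDED_PRE_DRUG_AKI"))
  }

  base_idx <- which(t <= as_hours(dose))
  base_idx <- if (length(base_idx)) max(base_idx) else NA_integer_
  post <- series[t > as_hours(dose) & t <= as_hours(dis), , drop = FALSE]
  candidate <- if (!is.na(base_idx)) {
    rbind(series[base_idx, , drop = FALSE], post)
  } else {
    post
  }
  hit <- earliest_event(
    find_absolute_rise(candidate, thresholds, from_time = dose),
    find_ratio_rise(candidate, thresholds, from_time = dose)
  )
  baseline_value <- if (!is.na(base_idx)) series$value[base_idx] else NULL
  baseline_time <- if (!is.na(base_idx)) series$time[base_idx] else NULL
  if (!is.null(hit)) {
    return(result("AKI_POST_DRUG", onset = hit, baseline_value = baseline_value, baseline_time = baseline_time))
  }
  if (!is.na(base_idx) && nrow(post) > 0L) {
    return(result("NO_AKI", baseline_value = baseline_value, baseline_time = baseline_time))
  }
  result("UNASSESSABLE", baseline_value = baseline_value, baseline_time = baseline_time)
}

#' Reference adjudication by exhaustive pair enumeration
#'
#' Same contract as [adjudicate()], implemented as a plain quadratic scan over
#' every ordered measurement pair with no early exit; used as an independent
#' oracle in the test suite.
#'
#' @inheritParams adjudicate
#' @return an `aki_adjudication`.
#' @export
brute_force_adjudicate <- function(patient, exposure, series,
                                   thresholds = detection_thresholds()) {
  adm <- patient$admission_time
  dis <- patient$discharge_time
  dose <- exposure$first_dose_time
  if (as_hours(dose) < as_hours(adm) || as_hours(dose) > as_hours(dis)) {
    stop_akiphen("exposure", sprintf(
      "first_dose_time outside admission interval for patient %s", patient$patient_id
    ))
  }
  result <- function(status, onset = NULL, baseline_value = NULL, baseline_time = NULL) {
    structure(
      list(
        patient_id = patient$patient_id, status = status, onset = onset,
        baseline_value = baseline_value, baseline_time = baseline_time
      ),
      class = "aki_adjudication"
    )
  }

  all_events <- function(sub, from_time) {
    tt <- as_hours(sub$time)
    vv <- sub$value
    events <- list()
    n <- length(tt)
    if (n >= 2L) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (tt[i] >= tt[j]) next
          if (as_hours(from_time) > tt[j]) next
          gap <- tt[j] - tt[i]
          if (gap <= thresholds$window_abs_hours && vv[j] - vv[i] >= thresholds$delta_abs) {
            events[[length(events) + 1L]] <- list(
              i = i, j = j, crit = "absolute_48h", rise = vv[j] - vv[i]
            )
          }
          if (gap <= thresholds$window_ratio_hours && vv[j] / vv[i] >= thresholds$ratio) {
            events[[length(events) + 1L]] <- list(
              i = i, j = j, crit = "ratio_7d", rise = vv[j] / vv[i]
            )
          }
        }
      }
    }
    if (!length(events)) return(NULL)
    # earliest later time; absolute_48h beats ratio_7d on an exact tie;
    # within a criterion the largest rise then earliest partner wins
    tj <- vapply(events, function(e) tt[e$j], 0)
    crit_rank <- vapply(events, function(e) match(e$crit, c("absolute_48h", "ratio_7d")), 0L)
    rise <- vapply(events, function(e) e$rise, 0)
    ti <- vapply(events, function(e) tt[e$i], 0)
    best <- order(tj, crit_rank, -rise, ti)[1L]
    e <- events[[best]]
    onset_event(sub$time[e$i], sub$time[e$j], vv[e$i], vv[e$j], e$crit)
  }

  if (isTRUE(patient$aki_before_admission)) {
    return(result("EXCLUDED_PRE_ADMISSION"))
  }
  t <- as_hours(series$time)
  pre <- series[t >= as_hours(adm) & t < as_hours(dose), , drop = FALSE]
  if (!is.null(all_events(pre, adm))) {
    return(result("EXCLUDED_PRE_DRUG_AKI"))
  }
  base_idx <- which(t <= as_hours(dose))
  base_idx <- if (length(base_idx)) max(base_idx) else NA_integer_
  post <- series[t > as_hours(dose) & t <= as_hours(dis), , drop = FALSE]
  candidate <- if (!is.na(base_idx)) rbind(series[base_idx, , drop = FALSE], post) else post
  hit <- all_events(candidate, dose)
  baseline_value <- if (!is.na(base_idx)) series$value[base_idx] else NULL
  baseline_time <- if (!is.na(base_idx)) series$time[base_idx] else NULL
  if (!is.null(hit)) {
    return(result("AKI_POST_DRUG", onset = hit, baseline_value = baseline_value, baseline_time = baseline_time))
  }
  if (!is.na(base_idx) && nrow(post) > 0L) {
    return(result("NO_AKI", baseline_value = baseline_value, baseline_time = baseline_time))
  }
  result("UNASSESSABLE", baseline_value = baseline_value, baseline_time = baseline_time)
}

#' Adjudicate every exposed patient in a cohort
#'
#' @param cohort an `aki_cohort` from [load_cohort()] or [simulate_cohort()].
#' @param thresholds a [detection_thresholds()] object.
#' @return data.frame with one row per exposed patient: `patient_id`,
#'   `status`, `onset_time`, `criterion`, `baseline_value`, `baseline_time`.
#' @export
adjudicate_cohort <- function(cohort, thresholds = detection_thresholds()) {
  stopifnot(inherits(cohort, "aki_cohort"))
  exp_ <- cohort$exposures
  pat <- cohort$patients
  scr_split <- split(
    cohort$creatinine[, c("time", "value")],
    factor(cohort$creatinine$patient_id, levels = exp_$patient_id)
  )
  rows <- lapply(seq_len(nrow(exp_)), function(k) {
    pid <- exp_$patient_id[k]
    p <- pat[match(pid, pat$patient_id), ]
    s <- scr_split[[pid]]
    if (is.null(s)) s <- data.frame(time = pat$admission_time[0], value = numeric(0))
    a <- adjudicate(p, exp_[k, ], s, thresholds)
    data.frame(
      patient_id = pid,
      status = a$status,
      onset_time = if (!is.null(a$onset)) format_timestamp(a$onset$later_time) else NA_character_,
      criterion = if (!is.null(a$onset)) a$onset$criterion else NA_character_,
      baseline_value = if (!is.null(a$baseline_value)) a$baseline_value else NA_real_,
      baseline_time = if (!is.null(a$baseline_time)) format_timestamp(a$baseline_time) else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Cohort AKI incidence among analyzable patients
#'
#' Analyzable patients are those adjudicated `AKI_POST_DRUG` or `NO_AKI`;
#' excluded and unassessable patients do not enter the denominator.
#'
#' @param adjudications data.frame from [adjudicate_cohort()] or a character
#'   vector of statuses.
#' @return list with `n_aki`, `n_analyzable` and `proportion`.
#' @export
cohort_incidence <- function(adjudications) {
  status <- if (is.data.frame(adjudications)) adjudications$status else adjudications
  if (!length(status)) stop_akiphen("empty", "no adjudications supplied")
  if (!all(status %in% AKI_STATUSES)) {
    stop_akiphen("status", "unknown adjudication status")
  }
  n_aki <- sum(status == "AKI_POST_DRUG")
  n_analyzable <- n_aki + sum(status == "NO_AKI")
  if (n_analyzable == 0L) {
    stop_akiphen("no_analyzable", "no analyzable patients (all excluded or unassessable)")
  }
  list(n_aki = n_aki, n_analyzable = n_analyzable, proportion = n_aki / n_analyzable)
}

#' @export
print.aki_adjudication <- function(x, ...) {
  cat(sprintf("patient %s: %s", x$patient_id, x$status))
  if (!is.null(x$onset)) {
    cat(sprintf(
      " (%s: %.1f -> %.1f umol/L)", x$onset$criterion,
      x$onset$earlier_value, x$onset$later_value
    ))
  }
  cat("\n")
  invisible(x)
}
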
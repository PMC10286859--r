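# Creatinine unit handling. Canonical internal unit is umol/L; the mg/dL
# conversion factor 88.4 is the standard molar-mass factor (0.3 mg/dL ->
# 26.52 umol/L).

SCR_UNITS <- c("umol_per_L", "mg_per_dL")
MG_DL_TO_UMOL_L <- 88.4

#' Convert serum-creatinine values between umol/L and mg/dL
#'
#' mg/dL values are multiplied by 88.4 to obtain umol/L; the inverse divides.
#' Converting a value to its own unit is the identity.
#'
#' @param value numeric vector of positive creatinine values.
#' @param from_unit,to_unit unit symbols, one of `"umol_per_L"` or
#'   `"mg_per_dL"`.
#' @return numeric vector in `to_unit`.
#' @examples
#' convert_creatinine(0.3, "mg_per_dL", "umol_per_L")  # 26.52
#' @export
convert_creatinine <- function(value, from_unit, to_unit) {
  check_unit(from_unit)
  check_unit(to_unit)
  if (any(!is.finite(value) | value <= 0)) {
    stop_akiphen("invalid_value", "creatinine values must be positive and finite")
  }
  if (from_unit == to_unit) {
    return(value)
  }
  if (from_unit == "mg_per_dL") value * MG_DL_TO_UMOL_L else value / MG_DL_TO_UMOL_L
}

check_unit <- function(unit) {
  if (length(unit) != 1L || !unit %in% SCR_UNITS) {
    stop_akiphen(
      "unknown_unit",
      sprintf(
        "unknown creatinine unit '%s'; expected one of: %s",
        paste(unit, collapse = ", "), paste(SCR_UNITS, collapse = ", ")
      )
    )
  }
  invisible(unit)
}

# Typed condition constructor used throughout: class akiphen_<what>_error.
stop_akiphen <- function(what, message, ...) {
  cond <- structure(
    class = c(paste0("akiphen_", what, "_error"), "akiphen_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

warn_akiphen <- function(what, message) {
  warning(warningCondition(message,
    class = c(paste0("akiphen_", what, "_warning"), "akiphen_warning")
  ))
}
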
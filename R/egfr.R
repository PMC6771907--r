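#' Estimated glomerular filtration rate (Japanese coefficient equation)
#'
#' Converts a serum creatinine measurement into an estimated glomerular
#' filtration rate (eGFR, mL/min/1.73 m^2) using the creatinine-based
#' Japanese equation: 194 * creatinine^-1.094 * age^-0.287, multiplied by
#' 0.739 for women.
#'
#' @param creatinine Serum creatinine in mg/dL; must be positive.
#' @param age Age in years; must be >= 18.
#' @param sex Character vector with values `"male"` or `"female"`.
#' @return Numeric vector of eGFR values in mL/min/1.73 m^2.
#' @examples
#' compute_egfr(1.0, 50, "male")
#' compute_egfr(1.0, 50, "female") / compute_egfr(1.0, 50, "male")  # 0.739
#' @export
compute_egfr <- function(creatinine, age, sex) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("creatinine must be positive and finite")
  if (any(!is.finite(age)) || any(age < 18))
    stop("age must be >= 18 years")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  out <- 194 * creatinine^(-1.094) * age^(-0.287)
  out[sex == "female"] <- out[sex == "female"] * 0.739
  out
}

# Invert the eGFR equation: creatinine giving a target eGFR for age/sex.
invert_egfr <- function(egfr, age, sex) {
  sexfac <- ifelse(as.character(sex) == "female", 0.739, 1)
  (egfr / (194 * age^(-0.287) * sexfac))^(-1 / 1.094)
}

#' Classify renal function preservation (RFP)
#'
#' Primary definition: RFP holds when the follow-up eGFR shows no change or
#' an increase from baseline (`followup >= baseline`). Sensitivity
#' definition: RFP holds when the relative change exceeds -5%
#' (`(followup - baseline) / baseline > -0.05`). Comparisons are performed
#' at full floating precision; no rounding is applied.
#'
#' @param baseline_egfr,followup_egfr Positive eGFR values
#'   (mL/min/1.73 m^2).
#' @param mode `"primary"` or `"sensitivity"`.
#' @return Logical vector; `TRUE` means renal function was preserved.
#' @examples
#' classify_rfp(70, 70)                        # TRUE: no change counts
#' classify_rfp(80, 76.5, mode = "sensitivity") # TRUE: -4.4% > -5%
#' @export
classify_rfp <- function(baseline_egfr, followup_egfr,
                         mode = c("primary", "sensitivity")) {
  mode <- match.arg(mode)
  if (any(!is.finite(baseline_egfr)) || any(baseline_egfr <= 0) ||
      any(!is.finite(followup_egfr)) || any(followup_egfr <= 0))
    stop("eGFR values must be positive and finite")
  if (mode == "primary") followup_egfr >= baseline_egfr
  else (followup_egfr - baseline_egfr) / baseline_egfr > -0.05
}

#' Select the baseline or follow-up measurement for one patient
#'
#' Baseline: the latest in-window value at or before the index date (window
#' spans `baseline_window_days` before the index). Follow-up: among values
#' inside the follow-up window, the one whose date is closest to the target
#' (index + `followup_target_days`); at an exact tie in distance the earlier
#' date wins. Dates are integer days relative to the index date (index = 0).
#'
#' @param dates Integer days relative to the index date.
#' @param values Measurement values aligned with `dates`.
#' @param window `"baseline"` or `"followup"`.
#' @param config An [eligibility_config()].
#' @return A list with `value` and `date`, or `NULL` when no in-window
#'   measurement exists.
#' @export
select_window_value <- function(dates, values,
                                window = c("baseline", "followup"),
                                config = eligibility_config()) {
  window <- match.arg(window)
  stopifnot(length(dates) == length(values))
  if (length(dates) == 0) return(NULL)
  if (window == "baseline") {
    keep <- dates >= -config$baseline_window_days & dates <= 0
    if (!any(keep)) return(NULL)
    i <- which(keep)[which.max(dates[keep])]
  } else {
    keep <- dates >= config$followup_window_min_days &
      dates <= config$followup_window_max_days
    if (!any(keep)) return(NULL)
    d <- abs(dates[keep] - config$followup_target_days)
    cand <- which(keep)[d == min(d)]
    i <- cand[which.min(dates[cand])]  # tie: earlier date
  }
  list(value = values[i], date = dates[i])
}
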
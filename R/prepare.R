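#' Eligibility configuration
#'
#' Window and validity parameters for cohort preparation. Dates are integer
#' days relative to the index date; the study's "6 months" and "9 to 15
#' months" are mapped to fixed day counts (183 / 274 / 457) to avoid
#' calendar ambiguity.
#'
#' @param creatinine_min,creatinine_max Valid creatinine range (mg/dL).
#' @param baseline_window_days Length of the baseline window before index.
#' @param followup_window_min_days,followup_window_max_days Follow-up
#'   window bounds after index.
#' @param followup_target_days Target day for follow-up selection (~12
#'   months).
#' @param min_exposure_days Required continuous exposure from index.
#' @param min_activity_days_before_index Required database activity before
#'   index.
#' @return An `eligibility_config` list.
#' @export
eligibility_config <- function(creatinine_min = 0.2, creatinine_max = 20,
                               baseline_window_days = 183,
                               followup_window_min_days = 274,
                               followup_window_max_days = 457,
                               followup_target_days = 365,
                               min_exposure_days = 274,
                               min_activity_days_before_index = 183) {
  cfg <- list(creatinine_min = creatinine_min, creatinine_max = creatinine_max,
              baseline_window_days = baseline_window_days,
              followup_window_min_days = followup_window_min_days,
              followup_window_max_days = followup_window_max_days,
              followup_target_days = followup_target_days,
              min_exposure_days = min_exposure_days,
              min_activity_days_before_index = min_activity_days_before_index)
  stopifnot(creatinine_min < creatinine_max,
            followup_window_min_days < followup_window_max_days,
            all(unlist(cfg) > 0))
  structure(cfg, class = "eligibility_config")
}

# Latest in-window value per patient (baseline) or nearest-to-target
# (follow-up), vectorised over a long measurement table. Tie at equal
# distance from the target day: earlier date wins.
select_window_table <- function(meas, window, config) {
  if (window == "baseline") {
    keep <- meas$date >= -config$baseline_window_days & meas$date <= 0
    m <- meas[keep, , drop = FALSE]
    o <- order(m$patient_id, -m$date, m$date)  # latest first within patient
  } else {
    keep <- meas$date >= config$followup_window_min_days &
      meas$date <= config$followup_window_max_days
    m <- meas[keep, , drop = FALSE]
    o <- order(m$patient_id, abs(m$date - config$followup_target_days), m$date)
  }
  m <- m[o, , drop = FALSE]
  m[!duplicated(m$patient_id), c("patient_id", "value", "date"), drop = FALSE]
}

#' Prepare the analysis-ready cohort
#'
#' Applies the eligibility filters in a fixed, logged order -- creatinine
#' validity, baseline creatinine present, follow-up creatinine present,
#' continuous exposure, database activity -- then derives baseline and
#' follow-up eGFR, the renal function preservation flag, and HbA1c change.
#' A patient fails the validity filter if any in-window creatinine
#' measurement lies outside the valid range. Patients lacking HbA1c values
#' are retained with `hba1c_change` set to `NA`.
#'
#' @param patients,measurements,exposures Raw tables as produced by
#'   [simulate_cohort()] / [write_sim_tables()] (or user files with the same
#'   headers).
#' @param config An [eligibility_config()].
#' @param rfp_mode `"primary"` or `"sensitivity"` (see [classify_rfp()]).
#' @return An object of class `rfp_cohort`: list with `records` (one row
#'   per eligible patient) and `attrition` (ordered filter log with columns
#'   filter, n_before, n_excluded, n_after).
#' @export
prepare_cohort <- function(patients, measurements, exposures,
                           config = eligibility_config(),
                           rfp_mode = c("primary", "sensitivity")) {
  rfp_mode <- match.arg(rfp_mode)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patients table")
  attrition <- data.frame(filter = character(), n_before = integer(),
                          n_excluded = integer(), n_after = integer(),
                          stringsAsFactors = FALSE)
  log_step <- function(name, before_ids, after_ids) {
    rbind(attrition, data.frame(
      filter = name, n_before = length(before_ids),
      n_excluded = length(before_ids) - length(after_ids),
      n_after = length(after_ids), stringsAsFactors = FALSE))
  }

  bad_rows <- !is.finite(measurements$value) | !is.finite(measurements$date)
  if (any(bad_rows)) {
    attrition <- rbind(attrition, data.frame(
      filter = "unparseable_measurement_rows",
      n_before = nrow(measurements), n_excluded = sum(bad_rows),
      n_after = nrow(measurements) - sum(bad_rows), stringsAsFactors = FALSE))
    measurements <- measurements[!bad_rows, , drop = FALSE]
  }

  cre <- measurements[measurements$analyte == "creatinine", , drop = FALSE]
  in_window <- (cre$date >= -config$baseline_window_days & cre$date <= 0) |
    (cre$date >= config$followup_window_min_days &
       cre$date <= config$followup_window_max_days)
  cre_w <- cre[in_window, , drop = FALSE]

  ids <- patients$patient_id

  # 1. creatinine validity
  invalid <- unique(cre_w$patient_id[cre_w$value < config$creatinine_min |
                                       cre_w$value > config$creatinine_max])
  keep <- setdiff(ids, invalid)
  attrition <- log_step("valid_creatinine_range", ids, keep); ids <- keep
  cre_valid <- cre_w[cre_w$patient_id %in% ids, , drop = FALSE]

  # 2. baseline creatinine present
  base_sel <- select_window_table(cre_valid, "baseline", config)
  keep <- ids[ids %in% base_sel$patient_id]
  attrition <- log_step("baseline_measurement_present", ids, keep); ids <- keep

  # 3. follow-up creatinine present
  fol_sel <- select_window_table(cre_valid, "followup", config)
  keep <- ids[ids %in% fol_sel$patient_id]
  attrition <- log_step("followup_measurement_present", ids, keep); ids <- keep

  # 4. continuous exposure to the assigned class for >= min_exposure_days
  trt <- patients$treatment_class[match(exposures$patient_id, patients$patient_id)]
  ok_exp <- exposures$patient_id[exposures$drug_class == trt &
                                   exposures$start_date <= 0 &
                                   exposures$end_date >= config$min_exposure_days]
  keep <- ids[ids %in% ok_exp]
  attrition <- log_step("continuous_exposure", ids, keep); ids <- keep

  # 5. database activity before index
  active <- patients$patient_id[patients$activity_start <=
                                  -config$min_activity_days_before_index]
  keep <- ids[ids %in% active]
  attrition <- log_step("database_activity", ids, keep); ids <- keep

  pat <- patients[match(ids, patients$patient_id), , drop = FALSE]
  bi <- match(ids, base_sel$patient_id)
  fi <- match(ids, fol_sel$patient_id)
  baseline_egfr <- compute_egfr(base_sel$value[bi], pat$age, pat$sex)
  followup_egfr <- compute_egfr(fol_sel$value[fi], pat$age, pat$sex)

  hba <- measurements[measurements$analyte == "HbA1c", , drop = FALSE]
  hb_base <- select_window_table(hba, "baseline", config)
  hb_fol <- select_window_table(hba, "followup", config)
  baseline_hba1c <- hb_base$value[match(ids, hb_base$patient_id)]
  followup_hba1c <- hb_fol$value[match(ids, hb_fol$patient_id)]

  records <- data.frame(
    pat[setdiff(names(pat), c("index_date", "activity_start"))],
    baseline_egfr = baseline_egfr,
    followup_egfr = followup_egfr,
    rfp = as.integer(classify_rfp(baseline_egfr, followup_egfr, rfp_mode)),
    baseline_hba1c = baseline_hba1c,
    followup_hba1c = followup_hba1c,
    hba1c_change = followup_hba1c - baseline_hba1c,
    stringsAsFactors = FALSE)
  rownames(records) <- NULL

  structure(list(records = records, attrition = attrition,
                 config = config, rfp_mode = rfp_mode),
            class = "rfp_cohort")
}

#' @export
print.rfp_cohort <- function(x, ...) {
  cat("Analysis cohort:", nrow(x$records), "patients",
      sprintf("(RFP mode: %s)\n", x$rfp_mode))
  nA <- sum(x$records$treatment_class == "A")
  cat(sprintf("  class A: %d, class B: %d\n", nA, nrow(x$records) - nA))
  cat(sprintf("  RFP rate: %.1f%%\n", 100 * mean(x$records$rfp)))
  cat("Attrition:\n")
  print(x$attrition, row.names = FALSE)
  invisible(x)
}

#' Read raw tables from CSV and prepare the cohort
#'
#' @param dir Directory containing patients.csv, measurements.csv and
#'   exposures.csv.
#' @inheritParams prepare_cohort
#' @return An `rfp_cohort` (see [prepare_cohort()]).
#' @export
prepare_cohort_csv <- function(dir, config = eligibility_config(),
                               rfp_mode = "primary") {
  prepare_cohort(
    utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "measurements.csv"), stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "exposures.csv"), stringsAsFactors = FALSE),
    config = config, rfp_mode = rfp_mode)
}
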
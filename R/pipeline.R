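#' Pipeline configuration
#'
#' Bundles every stage's settings into one reproducible run description.
#' Exactly one input source is used: a simulation config, or a directory of
#' raw CSV tables (patients.csv, measurements.csv, exposures.csv).
#'
#' @param simulation A [sim_config()], or `NULL` when reading files.
#' @param input_dir Directory with raw CSV tables, or `NULL` when
#'   simulating.
#' @param eligibility An [eligibility_config()].
#' @param propensity A [propensity_spec()].
#' @param rules A [screening_rules()].
#' @param learning_fraction Learning-set fraction for the stratified split.
#' @param rfp_mode `"primary"` or `"sensitivity"`.
#' @param search_variables Variables for the profile search.
#' @param grid Quantile levels for continuous thresholds.
#' @param bh_alpha BH significance level for validation.
#' @param require_benefit_bh See [validate_profiles()].
#' @param allow_list,deny_list Expert-review stand-ins (see
#'   [screen_profiles()]).
#' @param seed Master seed; also seeds the split and (when simulating)
#'   overrides the simulation config's seed.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = study_preset(),
                            input_dir = NULL,
                            eligibility = eligibility_config(),
                            propensity = propensity_spec(),
                            rules = screening_rules(),
                            learning_fraction = 0.70,
                            rfp_mode = c("primary", "sensitivity"),
                            search_variables = c("baseline_egfr", "duration",
                                                 "haemoglobin", "ldl",
                                                 "hyperlipidaemia",
                                                 "antithrombotic"),
                            grid = seq(0.1, 0.9, by = 0.1),
                            bh_alpha = 0.10,
                            require_benefit_bh = FALSE,
                            allow_list = NULL, deny_list = NULL,
                            seed = 1L, out_dir = NULL) {
  rfp_mode <- match.arg(rfp_mode)
  if (!is.null(input_dir) && !is.null(simulation))
    simulation <- NULL  # files win when both are given explicitly
  if (is.null(input_dir) && is.null(simulation))
    stop("provide either a simulation config or an input directory")
  structure(list(simulation = simulation, input_dir = input_dir,
                 eligibility = eligibility, propensity = propensity,
                 rules = rules, learning_fraction = learning_fraction,
                 rfp_mode = rfp_mode, search_variables = search_variables,
                 grid = grid, bh_alpha = bh_alpha,
                 require_benefit_bh = require_benefit_bh,
                 allow_list = allow_list, deny_list = deny_list,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full study pipeline
#'
#' Executes simulate (or load) -> prepare -> baseline comparison ->
#' propensity fit -> full-cohort class effects (renal outcome and HbA1c
#' change) -> stratified 70/30 split -> profile discovery on the learning
#' set -> hold-out validation with BH correction -> report rendering.
#' Reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @return A `study_report`: full-cohort effect estimates, the
#'   `profile_search` fit, validation results, rendered profile tables
#'   (renal and HbA1c outcomes), attrition log, balance table, pairwise
#'   profile overlap, and a provenance block. If `config$out_dir` is set,
#'   all tabular artifacts are also written as CSV plus a provenance JSON.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(
#'   simulation = study_preset(n_patients = 2000), seed = 1))
#' rep
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) {
    simcfg <- config$simulation
    simcfg$seed <- config$seed
    sim <- simulate_cohort(simcfg)
    raw <- sim[c("patients", "measurements", "exposures")]
    truth <- sim$truth
  } else {
    raw <- list(
      patients = utils::read.csv(file.path(config$input_dir, "patients.csv"),
                                 stringsAsFactors = FALSE),
      measurements = utils::read.csv(file.path(config$input_dir, "measurements.csv"),
                                     stringsAsFactors = FALSE),
      exposures = utils::read.csv(file.path(config$input_dir, "exposures.csv"),
                                  stringsAsFactors = FALSE))
    truth <- NULL
  }
  cohort <- prepare_cohort(raw$patients, raw$measurements, raw$exposures,
                           config$eligibility, config$rfp_mode)
  records <- cohort$records

  balance_covs <- intersect(
    c("age", "sex", "hospitalized", "baseline_egfr", "duration",
      "baseline_hba1c", "haemoglobin", "ldl", "charlson", "hyperlipidaemia",
      "hypertension", "antithrombotic", "neuropathy", "nephropathy",
      "retinopathy", "prior_regimen"),
    names(records))
  balance <- baseline_comparison(records, balance_covs)

  ps <- fit_propensity(records, config$propensity)

  full_effect_rfp <- class_effect_binary(records, ps$scores)
  cnt <- table(factor(records$treatment_class, c("A", "B")),
               factor(records$rfp, c(1, 0)))
  full_unadjusted <- unadjusted_or(cnt[1, 1], cnt[1, 2], cnt[2, 1], cnt[2, 2])
  full_effect_hba1c <- if (any(!is.na(records$hba1c_change)))
    class_effect_continuous(records, ps$scores) else NULL

  split <- stratified_split(records, split_config(config$learning_fraction,
                                                  config$seed))
  learn_scores <- ps$scores[split$learning_idx]
  valid_scores <- ps$scores[-split$learning_idx]

  search <- discover_profiles(split$learning, learn_scores,
                              config$search_variables, config$rules,
                              config$grid, config$allow_list,
                              config$deny_list)
  validation <- validate_profiles(search$screened, split$validation,
                                  valid_scores, config$rules,
                                  config$bh_alpha, config$require_benefit_bh)

  profile_table <- render_profile_table(search$screened, validation)
  hba1c_table <- render_hba1c_table(search$screened, validation,
                                    split, learn_scores, valid_scores)
  overlap <- profile_overlap(validation, split$learning)

  report <- structure(list(
    full_cohort = list(rfp_adjusted = full_effect_rfp,
                       rfp_unadjusted = full_unadjusted,
                       hba1c_adjusted = full_effect_hba1c),
    cohort = cohort, balance = balance, propensity = ps,
    search = search, validation = validation,
    profile_table = profile_table, hba1c_table = hba1c_table,
    overlap = overlap, truth = truth,
    provenance = list(seed = config$seed, rfp_mode = config$rfp_mode,
                      n_cohort = nrow(records),
                      learning_fraction = config$learning_fraction,
                      bh_alpha = config$bh_alpha,
                      package_version = as.character(utils::packageVersion("rfprofile")),
                      timestamp_utc = format(Sys.time(), tz = "UTC")),
    config = config), class = "study_report")
  if (!is.null(config$out_dir)) write_report_artifacts(report, config$out_dir)
  report
}

round_pct <- function(x) round(100 * x)  # round-half-even percentages

report_row <- function(report, bh_eff = NA_real_, bh_ben = NA_real_) {
  eff <- report$class_effect; ben <- report$class_benefit
  data.frame(
    n = report$n, pct = round_pct(report$size_fraction),
    aor = if (is.null(eff)) NA_real_ else round(eff$estimate, 1),
    aor_p = if (is.null(eff)) NA_real_ else round(eff$p_value, 4),
    aor_bh_p = round(bh_eff, 4),
    ratio = if (is.null(ben)) NA_real_ else round(ben$estimate, 1),
    ratio_p = if (is.null(ben)) NA_real_ else round(ben$p_value, 4),
    ratio_bh_p = round(bh_ben, 4))
}

#' Render the validated-profile table (renal outcome)
#'
#' One row per profile carried into validation, mirroring the standard
#' reporting layout: N (%), class effect (aOR, p, BH p) and class benefit
#' (ratio of aORs, p, BH p) for the learning and validation sets. Odds
#' ratios are rounded to 1 decimal, p-values to 4 decimals; percentages use
#' round-half-even.
#'
#' @param screened Ranked `credibility_report`s from the learning set.
#' @param validation Matching `validation_result`s.
#' @return data.frame, one row per profile (empty with the full column set
#'   when nothing was carried forward).
#' @export
render_profile_table <- function(screened, validation) {
  if (length(validation) == 0) {
    out <- data.frame(profile = character(), validated = logical())
    for (side in c("learning", "validation"))
      for (col in c("n", "pct", "aor", "aor_p", "aor_bh_p", "ratio",
                    "ratio_p", "ratio_bh_p"))
        out[[paste(side, col, sep = "_")]] <- numeric()
    return(out)
  }
  rows <- lapply(seq_along(validation), function(i) {
    v <- validation[[i]]
    lr <- report_row(screened[[i]])
    names(lr) <- paste("learning", names(lr), sep = "_")
    vr <- report_row(v$validation_report, v$bh_p_class_effect,
                     v$bh_p_class_benefit)
    names(vr) <- paste("validation", names(vr), sep = "_")
    cbind(data.frame(profile = v$profile$label, validated = v$validated,
                     stringsAsFactors = FALSE), lr, vr)
  })
  out <- do.call(rbind, rows)
  out$learning_aor_bh_p <- NULL  # BH correction applies to validation only
  out$learning_ratio_bh_p <- NULL
  rownames(out) <- NULL
  out
}

# HbA1c-change analogue of the profile table: adjusted mean differences
# within each carried profile on both datasets.
render_hba1c_table <- function(screened, validation, split,
                               learn_scores, valid_scores) {
  if (length(validation) == 0)
    return(data.frame(profile = character(), learning_adelta = numeric(),
                      learning_p = numeric(), validation_adelta = numeric(),
                      validation_p = numeric()))
  safe_delta <- function(data, m, scores) {
    eff <- try(class_effect_continuous(data[m, , drop = FALSE], scores[m]),
               silent = TRUE)
    ben <- try(class_benefit_continuous(data, m, scores), silent = TRUE)
    c(delta = if (inherits(eff, "try-error")) NA_real_ else round(eff$estimate, 2),
      p = if (inherits(eff, "try-error")) NA_real_ else round(eff$p_value, 4),
      bdelta = if (inherits(ben, "try-error")) NA_real_ else round(ben$estimate, 2),
      bp = if (inherits(ben, "try-error")) NA_real_ else round(ben$p_value, 4))
  }
  rows <- lapply(validation, function(v) {
    ml <- profile_membership(v$profile, split$learning)
    mv <- profile_membership(v$profile, split$validation)
    l <- safe_delta(split$learning, ml, learn_scores)
    vv <- safe_delta(split$validation, mv, valid_scores)
    data.frame(profile = v$profile$label,
               learning_adelta = l[["delta"]], learning_p = l[["p"]],
               learning_benefit_adelta = l[["bdelta"]],
               learning_benefit_p = l[["bp"]],
               validation_adelta = vv[["delta"]], validation_p = vv[["p"]],
               validation_benefit_adelta = vv[["bdelta"]],
               validation_benefit_p = vv[["bp"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pairwise membership overlap (% of the smaller profile) between carried
# profiles on the learning set.
profile_overlap <- function(validation, learning) {
  k <- length(validation)
  if (k < 2) return(NULL)
  mem <- lapply(validation, function(v) profile_membership(v$profile, learning))
  labs <- vapply(validation, function(v) v$profile$label, "")
  out <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- round_pct(sum(mem[[i]] & mem[[j]]) /
                             max(1, min(sum(mem[[i]]), sum(mem[[j]]))))
  out
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(report$cohort$records, "analysis_cohort.csv")
  w(report$cohort$attrition, "attrition.csv")
  w(report$balance, "balance_table.csv")
  w(summary(report$search), "discovered_profiles.csv")
  w(report$profile_table, "validation_results.csv")
  w(report$hba1c_table, "hba1c_results.csv")
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Study report ==\n")
  cat(sprintf("Cohort: %d patients (class A %d / class B %d), RFP mode '%s'\n",
              x$provenance$n_cohort,
              sum(x$cohort$records$treatment_class == "A"),
              sum(x$cohort$records$treatment_class == "B"), x$provenance$rfp_mode))
  cat(sprintf("RFP rate: %.1f%%\n", 100 * mean(x$cohort$records$rfp)))
  cat("Full-cohort class effect (RFP): ")
  print(x$full_cohort$rfp_adjusted)
  u <- x$full_cohort$rfp_unadjusted
  cat(sprintf("  unadjusted OR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              u$or, u$ci_low, u$ci_high, u$p_value))
  if (!is.null(x$full_cohort$hba1c_adjusted)) {
    cat("Full-cohort class effect (HbA1c change): ")
    print(x$full_cohort$hba1c_adjusted)
  }
  cat(sprintf("Profile search: %d evaluated, %d passed screening, %d carried\n",
              x$search$n_evaluated, x$search$n_passed, length(x$validation)))
  nv <- sum(vapply(x$validation, `[[`, TRUE, "validated"))
  cat(sprintf("Validated profiles: %d\n", nv))
  for (v in x$validation)
    cat(sprintf("  %s %s\n", if (v$validated) "*" else " ", v$profile$label))
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  list(full_cohort = object$full_cohort,
       profile_table = object$profile_table,
       hba1c_table = object$hba1c_table,
       attrition = object$cohort$attrition)
}

#' @export
plot.study_report <- function(x, ...) {
  plot(x$search, ...)
}
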
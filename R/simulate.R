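#' Covariate specification for the synthetic cohort generator
#'
#' @param name Column name.
#' @param kind `"continuous"`, `"binary"` or `"categorical"`.
#' @param ... Distribution parameters. Continuous: `dist` (`"normal"`,
#'   `"lognormal"` or `"uniform"`), with `mean`/`sd` (+ optional truncation
#'   `min`/`max`), `meanlog`/`sdlog`, or `min`/`max`. Binary: `prevalence`.
#'   Categorical: `levels` and `probs`.
#' @return A `cov_spec` list.
#' @export
cov_spec <- function(name, kind = c("continuous", "binary", "categorical"), ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  if (kind == "continuous") {
    pars$dist <- pars$dist %||% "normal"
    if (!pars$dist %in% c("normal", "lognormal", "uniform"))
      stop("unknown distribution kind '", pars$dist, "' for covariate ", name)
  }
  if (kind == "binary" && is.null(pars$prevalence))
    stop("binary covariate ", name, " needs a prevalence")
  if (kind == "categorical" &&
      (is.null(pars$levels) || is.null(pars$probs) ||
       length(pars$levels) != length(pars$probs)))
    stop("categorical covariate ", name, " needs matching levels and probs")
  structure(c(list(name = name, kind = kind), pars), class = "cov_spec")
}

#' Ground-truth benefit subgroup for the generator
#'
#' Members of the profile receive an additional treatment log odds ratio on
#' the renal outcome; overlapping profiles contribute additively on the
#' log-odds scale.
#'
#' @param criteria A list of 1-2 [criterion()] objects on generator
#'   covariates.
#' @param extra_treatment_log_or Additional log odds ratio of treatment on
#'   the outcome for profile members.
#' @return A `true_profile` list.
#' @export
true_profile <- function(criteria, extra_treatment_log_or) {
  if (inherits(criteria, "rfp_criterion")) criteria <- list(criteria)
  if (length(criteria) < 1 || length(criteria) > 2)
    stop("a profile has 1 or 2 criteria")
  stopifnot(all(vapply(criteria, inherits, TRUE, "rfp_criterion")))
  structure(list(criteria = criteria,
                 extra_treatment_log_or = extra_treatment_log_or),
            class = "true_profile")
}

#' Configuration of the synthetic claims-style cohort
#'
#' Defines the full generative truth: covariate distributions, the
#' confounded treatment-assignment model, the renal outcome model with
#' implanted benefit subgroups, the glycaemic (HbA1c change) outcome, and
#' the raw-table emission parameters.
#'
#' @param n_patients Number of patients (>= 1).
#' @param treated_fraction_target Marginal probability of treatment class A,
#'   strictly inside (0, 1); the assignment intercept is solved numerically
#'   to hit it.
#' @param covariate_specs List of [cov_spec()] objects.
#' @param confounding_coefficients Named log-odds contributions of
#'   covariates to treatment assignment. Categorical levels are addressed as
#'   `"name:level"`.
#' @param baseline_outcome_coefficients Named log-odds contributions of
#'   covariates to the renal outcome.
#' @param base_treatment_log_or Treatment log odds ratio on the renal
#'   outcome outside any implanted profile.
#' @param implanted_profiles List of [true_profile()] objects.
#' @param rfp_target_rate Marginal outcome prevalence the outcome intercept
#'   is solved to match (a modelling choice, ~0.40 by default).
#' @param hba1c_effect Mean treatment difference in HbA1c change
#'   (%-points); 0 by default (no glycaemic difference between classes).
#' @param hba1c_mean_change Mean HbA1c change in the comparator class.
#' @param hba1c_sd Residual SD of HbA1c change.
#' @param measurement_noise_sd SD (log scale) of noise applied to distractor
#'   lab measurements.
#' @param ineligible_fraction Fraction of patients given a deliberately
#'   ineligible record (invalid creatinine, missing follow-up, short
#'   exposure, or short database activity) to exercise attrition.
#' @param seed Master seed; per-stage streams are derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients,
                       treated_fraction_target = 0.19,
                       covariate_specs,
                       confounding_coefficients = numeric(),
                       baseline_outcome_coefficients = numeric(),
                       base_treatment_log_or = 0,
                       implanted_profiles = list(),
                       rfp_target_rate = 0.40,
                       hba1c_effect = 0,
                       hba1c_mean_change = -0.4,
                       hba1c_sd = 0.8,
                       measurement_noise_sd = 0.05,
                       ineligible_fraction = 0,
                       seed = 1L) {
  stopifnot(n_patients >= 1,
            treated_fraction_target > 0, treated_fraction_target < 1,
            rfp_target_rate > 0, rfp_target_rate < 1,
            ineligible_fraction >= 0, ineligible_fraction <= 1)
  if (inherits(implanted_profiles, "true_profile"))
    implanted_profiles <- list(implanted_profiles)
  cov_names <- vapply(covariate_specs, `[[`, "", "name")
  base_name <- function(x) {
    b <- sub(":.*$", "", x)
    b[b == "age_cat"] <- "age"      # derived encodings share the propensity
    b[b == "hba1c_cat"] <- "hba1c"  # spec's fixed cut points
    b
  }
  for (nm in names(confounding_coefficients))
    if (!base_name(nm) %in% cov_names)
      stop("confounding coefficient on unknown covariate: ", nm)
  for (nm in names(baseline_outcome_coefficients))
    if (!base_name(nm) %in% cov_names)
      stop("outcome coefficient on unknown covariate: ", nm)
  for (pr in implanted_profiles)
    for (cr in pr$criteria)
      if (!cr$variable %in% cov_names)
        stop("implanted profile uses unknown covariate: ", cr$variable)
  structure(list(
    n_patients = as.integer(n_patients),
    treated_fraction_target = treated_fraction_target,
    covariate_specs = covariate_specs,
    confounding_coefficients = confounding_coefficients,
    baseline_outcome_coefficients = baseline_outcome_coefficients,
    base_treatment_log_or = base_treatment_log_or,
    implanted_profiles = implanted_profiles,
    rfp_target_rate = rfp_target_rate,
    hba1c_effect = hba1c_effect,
    hba1c_mean_change = hba1c_mean_change,
    hba1c_sd = hba1c_sd,
    measurement_noise_sd = measurement_noise_sd,
    ineligible_fraction = ineligible_fraction,
    seed = as.integer(seed)), class = "sim_config")
}

default_covariate_specs <- function() {
  list(
    cov_spec("age", "continuous", mean = 67, sd = 11, min = 18, max = 94),
    cov_spec("sex", "categorical", levels = c("male", "female"),
             probs = c(0.60, 0.40)),
    cov_spec("hospitalized", "binary", prevalence = 0.22),
    cov_spec("egfr", "continuous", mean = 68, sd = 18, min = 20, max = 130),
    cov_spec("duration", "continuous", mean = 5, sd = 3.5, min = 0.1, max = 25),
    cov_spec("hba1c", "continuous", mean = 7.9, sd = 1.2, min = 5.2, max = 13),
    cov_spec("haemoglobin", "continuous", mean = 13.5, sd = 1.8, min = 7, max = 19),
    cov_spec("ldl", "continuous", mean = 110, sd = 30, min = 30, max = 250),
    cov_spec("charlson", "continuous", mean = 1.9, sd = 1.4, min = 0, max = 10),
    cov_spec("hyperlipidaemia", "binary", prevalence = 0.45),
    cov_spec("hypertension", "binary", prevalence = 0.52),
    cov_spec("antithrombotic", "binary", prevalence = 0.40),
    cov_spec("neuropathy", "binary", prevalence = 0.38),
    cov_spec("nephropathy", "binary", prevalence = 0.05),
    cov_spec("retinopathy", "binary", prevalence = 0.15),
    cov_spec("diuretics", "binary", prevalence = 0.12),
    cov_spec("beta_blocker", "binary", prevalence = 0.10),
    cov_spec("ccb", "binary", prevalence = 0.25),
    cov_spec("ras", "binary", prevalence = 0.30),
    cov_spec("prior_regimen", "categorical",
             levels = c("naive", "oad1", "oad2plus", "insulin"),
             probs = c(0.40, 0.30, 0.20, 0.10)))
}

default_confounding <- function() {
  c("age_cat:45-64" = -0.55, "age_cat:65+" = -1.1,
    "hba1c_cat:6.5-<7" = 0.35, "hba1c_cat:>=7" = 0.8,
    egfr = 0.018, duration = 0.05,
    hyperlipidaemia = 0.5, hypertension = 0.5, neuropathy = 0.8,
    hospitalized = -1.0, charlson = 0.10,
    "prior_regimen:oad2plus" = 0.8, "prior_regimen:insulin" = 0.4)
}

default_outcome_coefficients <- function() {
  c(egfr = -0.012, age = -0.01, hba1c = -0.12, nephropathy = -0.5,
    hypertension = -0.2, charlson = -0.08)
}

#' Cohort presets mirroring the study's shape
#'
#' `study_preset()`: n = 5247 patients, treated fraction 0.19, confounded
#' assignment, ~40% marginal outcome rate, a small beneficial base class
#' effect (log OR = log 1.1) and one implanted benefit subgroup
#' (hyperlipidaemia absent AND antithrombotic use, extra log OR = log 2.5,
#' ~22% prevalence). `null_preset()`: same cohort structure with no
#' treatment effect anywhere (base log OR 0, no implanted profiles).
#'
#' @param seed Master seed.
#' @param n_patients Cohort size.
#' @param ineligible_fraction Fraction of deliberately ineligible patients.
#' @return A [sim_config()].
#' @export
study_preset <- function(seed = 1L, n_patients = 5247,
                         ineligible_fraction = 0) {
  sim_config(
    n_patients = n_patients,
    treated_fraction_target = 0.19,
    covariate_specs = default_covariate_specs(),
    confounding_coefficients = default_confounding(),
    baseline_outcome_coefficients = default_outcome_coefficients(),
    base_treatment_log_or = log(1.1),
    implanted_profiles = list(true_profile(
      list(criterion("hyperlipidaemia", "=", 0),
           criterion("antithrombotic", "=", 1)),
      extra_treatment_log_or = log(2.5))),
    rfp_target_rate = 0.40,
    ineligible_fraction = ineligible_fraction,
    seed = seed)
}

#' @rdname study_preset
#' @export
null_preset <- function(seed = 1L, n_patients = 5247,
                        ineligible_fraction = 0) {
  cfg <- study_preset(seed = seed, n_patients = n_patients,
                      ineligible_fraction = ineligible_fraction)
  cfg$base_treatment_log_or <- 0
  cfg$implanted_profiles <- list()
  cfg
}

#' Draw baseline covariates
#'
#' Each covariate is drawn i.i.d. from its specification; continuous normal
#' covariates with truncation bounds are drawn by inverse-CDF truncation.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A data.frame with `n_patients` rows.
#' @export
draw_covariates <- function(config) {
  n <- config$n_patients
  with_stage_seed(config$seed, "covariates", {
    cols <- lapply(config$covariate_specs, function(sp) {
      switch(sp$kind,
        continuous = switch(sp$dist,
          normal = {
            lo <- sp$min %||% -Inf; hi <- sp$max %||% Inf
            u <- stats::runif(n, stats::pnorm(lo, sp$mean, sp$sd),
                              stats::pnorm(hi, sp$mean, sp$sd))
            stats::qnorm(u, sp$mean, sp$sd)
          },
          lognormal = stats::rlnorm(n, sp$meanlog, sp$sdlog),
          uniform = stats::runif(n, sp$min, sp$max)),
        binary = as.integer(stats::runif(n) < sp$prevalence),
        categorical = sample(sp$levels, n, replace = TRUE, prob = sp$probs))
    })
    names(cols) <- vapply(config$covariate_specs, `[[`, "", "name")
    data.frame(patient_id = sprintf("P%05d", seq_len(n)), cols,
               stringsAsFactors = FALSE)
  })
}

# Linear predictor over named coefficients; "name:level" addresses a
# categorical dummy. The derived names "age_cat:*" and "hba1c_cat:*" use
# the same fixed cut points as the propensity specification (age 45/65;
# HbA1c 6.5/7), so confounding expressed through them is exactly removable
# by the analysis's confounder list.
coef_linear_predictor <- function(covariates, coefs) {
  eta <- numeric(nrow(covariates))
  for (nm in names(coefs)) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      base <- if (parts[1] == "age_cat") {
        as.character(cut(covariates$age, c(18, 45, 65, Inf), right = FALSE,
                         labels = c("18-44", "45-64", "65+"),
                         include.lowest = TRUE))
      } else if (parts[1] == "hba1c_cat") {
        as.character(cut(covariates$hba1c, c(-Inf, 6.5, 7, Inf),
                         right = FALSE, labels = c("<6.5", "6.5-<7", ">=7")))
      } else covariates[[parts[1]]]
      x <- as.numeric(base == parts[2])
    } else {
      x <- as.numeric(covariates[[nm]])
    }
    eta <- eta + coefs[[nm]] * x
  }
  eta
}

solve_intercept <- function(eta, target) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("cannot solve intercept: degenerate coefficients")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Assign treatment classes with confounding
#'
#' Class A is assigned with probability `plogis(alpha + sum(coef * x))`; the
#' intercept `alpha` is solved numerically so the marginal treated fraction
#' matches `treated_fraction_target` (in expectation, within 0.005).
#'
#' @param covariates Output of [draw_covariates()].
#' @param config A [sim_config()].
#' @return Character vector of `"A"` (treated class) / `"B"`.
#' @export
assign_treatment <- function(covariates, config) {
  eta <- coef_linear_predictor(covariates, config$confounding_coefficients)
  alpha <- solve_intercept(eta, config$treated_fraction_target)
  with_stage_seed(config$seed, "treatment", {
    ifelse(stats::runif(nrow(covariates)) < stats::plogis(alpha + eta), "A", "B")
  })
}

#' Generate patient outcomes
#'
#' The renal outcome (RFP) is Bernoulli with
#' `logit p = b0 + sum(outcome_coefs * x) + t * (base_log_or + sum extra)`,
#' where the extra terms come from implanted profiles containing the patient
#' (additive on the log-odds scale for overlapping profiles); `b0` is solved
#' so the marginal rate matches `rfp_target_rate`. HbA1c change is Gaussian
#' with a treatment mean shift of `hba1c_effect`.
#'
#' @param covariates,treatment Outputs of the previous stages.
#' @param config A [sim_config()].
#' @return data.frame with columns `rfp` (0/1) and `hba1c_change`.
#' @export
generate_outcomes <- function(covariates, treatment, config) {
  t <- as.numeric(treatment == "A")
  eta <- coef_linear_predictor(covariates, config$baseline_outcome_coefficients)
  extra <- numeric(nrow(covariates))
  for (pr in config$implanted_profiles) {
    m <- profile_membership(rfp_profile(pr$criteria), covariates)
    extra <- extra + pr$extra_treatment_log_or * as.numeric(m)
  }
  tlin <- t * (config$base_treatment_log_or + extra)
  b0 <- solve_intercept(eta + tlin, config$rfp_target_rate)
  p <- stats::plogis(b0 + eta + tlin)
  with_stage_seed(config$seed, "outcomes", {
    rfp <- as.integer(stats::runif(length(p)) < p)
    hba1c_change <- stats::rnorm(length(p),
                                 config$hba1c_mean_change + t * config$hba1c_effect,
                                 config$hba1c_sd)
    data.frame(rfp = rfp, hba1c_change = hba1c_change)
  })
}

#' Emit raw claims-style tables
#'
#' Produces the three raw tables the preparation stage consumes: a patient
#' table, a long measurement table (creatinine and HbA1c, with distractor
#' measurements placed so window selection is exercised but never changes
#' the chosen value), and an exposure table. Baseline creatinine is
#' back-solved from the intended baseline eGFR; follow-up creatinine from
#' the intended follow-up eGFR, which encodes the drawn RFP flag
#' (multiplicative change >= 1 for preserved, < 1 otherwise, with a share of
#' declines shallower than 5% so the sensitivity definition is non-trivial).
#' A configurable fraction of patients receives one deliberately ineligible
#' record; the injected violations are recorded in the returned truth table.
#'
#' @param covariates,treatment,outcomes Outputs of the previous stages.
#' @param config A [sim_config()].
#' @return List with `patients`, `measurements`, `exposures`, `truth`
#'   data.frames.
#' @export
emit_raw_tables <- function(covariates, treatment, outcomes, config) {
  n <- nrow(covariates)
  with_stage_seed(config$seed, "measurements", {
    baseline_day <- -sample(1:60, n, replace = TRUE)
    followup_day <- sample(335:395, n, replace = TRUE)
    distract_base_day <- -sample(130:183, n, replace = TRUE)
    distract_follow_day <- sample(c(276:300, 430:456), n, replace = TRUE)
    change <- ifelse(outcomes$rfp == 1,
                     1 + stats::runif(n, 0, 0.15),
                     1 - stats::runif(n, 0.005, 0.20))
    noise <- exp(stats::rnorm(2 * n, 0, config$measurement_noise_sd))
    baseline_egfr <- covariates$egfr
    followup_egfr <- baseline_egfr * change
    cr_base <- invert_egfr(baseline_egfr, covariates$age, covariates$sex)
    cr_follow <- invert_egfr(followup_egfr, covariates$age, covariates$sex)
    hba1c_base <- covariates$hba1c
    hba1c_follow <- hba1c_base + outcomes$hba1c_change

    patients <- data.frame(
      patient_id = covariates$patient_id,
      treatment_class = treatment,
      index_date = 0L,
      activity_start = -sample(200:420, n, replace = TRUE),
      covariates[setdiff(names(covariates), "patient_id")],
      stringsAsFactors = FALSE)

    measurements <- rbind(
      data.frame(patient_id = covariates$patient_id, analyte = "creatinine",
                 value = cr_base, date = baseline_day),
      data.frame(patient_id = covariates$patient_id, analyte = "creatinine",
                 value = cr_base * noise[1:n], date = distract_base_day),
      data.frame(patient_id = covariates$patient_id, analyte = "creatinine",
                 value = cr_follow, date = followup_day),
      data.frame(patient_id = covariates$patient_id, analyte = "creatinine",
                 value = cr_follow * noise[(n + 1):(2 * n)],
                 date = distract_follow_day),
      data.frame(patient_id = covariates$patient_id, analyte = "HbA1c",
                 value = hba1c_base, date = baseline_day),
      data.frame(patient_id = covariates$patient_id, analyte = "HbA1c",
                 value = hba1c_follow, date = followup_day))

    exposures <- data.frame(
      patient_id = covariates$patient_id,
      drug_class = treatment,
      start_date = 0L,
      end_date = sample(300:460, n, replace = TRUE))

    violation <- rep("none", n)
    if (config$ineligible_fraction > 0) {
      hit <- with_stage_seed(config$seed, "ineligible", {
        h <- stats::runif(n) < config$ineligible_fraction
        v <- sample(c("invalid_creatinine", "missing_followup",
                      "short_exposure", "short_activity"), n, replace = TRUE)
        list(h = h, v = v)
      })
      violation[hit$h] <- hit$v[hit$h]
      bad <- which(violation == "invalid_creatinine")
      measurements$value[bad] <- 0.05  # first block holds baseline creatinine
      mf <- which(violation == "missing_followup")
      drop_rows <- c(2L * n + mf, 3L * n + mf)  # both follow-up creatinine rows
      if (length(mf)) measurements <- measurements[-drop_rows, ]
      exposures$end_date[violation == "short_exposure"] <- 100L
      patients$activity_start[violation == "short_activity"] <- -30L
    }

    truth <- data.frame(
      patient_id = covariates$patient_id,
      baseline_egfr = baseline_egfr,
      followup_egfr = followup_egfr,
      rfp = outcomes$rfp,
      hba1c_change = outcomes$hba1c_change,
      violation = violation,
      stringsAsFactors = FALSE)

    rownames(measurements) <- NULL
    list(patients = patients, measurements = measurements,
         exposures = exposures, truth = truth)
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs the four generator stages (covariates, confounded treatment
#' assignment, outcomes, raw-table emission) on independent RNG streams
#' derived from the master seed. Identical configs give byte-identical
#' tables.
#'
#' @param config A [sim_config()].
#' @return An object of class `rfp_sim`: list with `patients`,
#'   `measurements`, `exposures`, `truth` and the `config`.
#' @examples
#' sim <- simulate_cohort(study_preset(seed = 1, n_patients = 500))
#' sim
#' @export
simulate_cohort <- function(config) {
  covariates <- draw_covariates(config)
  treatment <- assign_treatment(covariates, config)
  outcomes <- generate_outcomes(covariates, treatment, config)
  raw <- emit_raw_tables(covariates, treatment, outcomes, config)
  structure(c(raw, list(config = config)), class = "rfp_sim")
}

#' @export
print.rfp_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$patients), "patients\n")
  cat("  treatment class A:", sum(x$patients$treatment_class == "A"),
      sprintf("(%.1f%%)\n", 100 * mean(x$patients$treatment_class == "A")))
  cat("  RFP rate (intended):", sprintf("%.1f%%\n", 100 * mean(x$truth$rfp)))
  cat("  implanted profiles:", length(x$config$implanted_profiles), "\n")
  cat("  measurements:", nrow(x$measurements), "rows\n")
  invisible(x)
}

#' Write the three raw tables as CSV files
#'
#' @param sim An `rfp_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (patients.csv, measurements.csv,
#'   exposures.csv).
#' @export
write_sim_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("patients.csv", "measurements.csv", "exposures.csv"))
  utils::write.csv(sim$patients, paths[1], row.names = FALSE)
  utils::write.csv(sim$measurements, paths[2], row.names = FALSE)
  utils::write.csv(sim$exposures, paths[3], row.names = FALSE)
  invisible(paths)
}
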
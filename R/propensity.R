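#' Propensity model specification
#'
#' Names the confounders entering the treatment-assignment (propensity)
#' model and how they are encoded. Age and baseline HbA1c are categorised
#' with fixed cut points (age 18-44 / 45-64 / >=65; HbA1c <6.5 / 6.5-<7 /
#' >=7) with the first category as the documented reference level; baseline
#' eGFR enters as a continuous term. Terms absent from the analysis table
#' raise an error.
#'
#' @param terms Character vector of covariate names. The special names
#'   `"age_cat"` and `"hba1c_cat"` are derived from `age` and
#'   `baseline_hba1c` (falling back to a raw `hba1c` column).
#' @return A `propensity_spec` object.
#' @export
propensity_spec <- function(terms = c("age_cat", "hospitalized",
                                      "baseline_egfr", "hba1c_cat",
                                      "charlson", "sex", "hyperlipidaemia",
                                      "hypertension", "diuretics",
                                      "beta_blocker", "ccb", "ras",
                                      "neuropathy", "nephropathy",
                                      "retinopathy", "prior_regimen")) {
  structure(list(terms = terms), class = "propensity_spec")
}

# Build the encoded model frame for a propensity spec.
propensity_frame <- function(records, spec) {
  out <- list()
  for (tm in spec$terms) {
    if (tm == "age_cat") {
      if (!"age" %in% names(records)) stop("spec term age_cat needs an 'age' column")
      out$age_cat <- cut(records$age, c(18, 45, 65, Inf), right = FALSE,
                         labels = c("18-44", "45-64", "65+"),
                         include.lowest = TRUE)
    } else if (tm == "hba1c_cat") {
      src <- if ("baseline_hba1c" %in% names(records)) records$baseline_hba1c
             else records$hba1c
      if (is.null(src)) stop("spec term hba1c_cat needs an HbA1c column")
      out$hba1c_cat <- cut(src, c(-Inf, 6.5, 7, Inf), right = FALSE,
                           labels = c("<6.5", "6.5-<7", ">=7"))
    } else {
      if (!tm %in% names(records))
        stop("propensity spec term not found in analysis table: ", tm)
      v <- records[[tm]]
      out[[tm]] <- if (is.character(v)) factor(v) else v
    }
  }
  if (length(out) == 0)
    return(data.frame(row.names = seq_len(nrow(records))))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment-class membership
#' (class A vs B) on the spec's encoded confounders. Scores are the fitted
#' probabilities of class A and are reused globally by all downstream
#' effect models (regression adjustment; no matching or weighting). Rows
#' with missing spec covariates are dropped with a logged count.
#' Non-convergence or separation triggers a ridge-stabilised refit
#' (penalty 1e-4), flagged in the diagnostics.
#'
#' @param cohort An `rfp_cohort` or an analysis records data.frame.
#' @param spec A [propensity_spec()].
#' @return A `propensity_model`: coefficients, per-patient `scores` in
#'   (0,1), `loglik`, `converged`, `ridge`, `n_dropped`.
#' @export
fit_propensity <- function(cohort, spec = propensity_spec()) {
  records <- if (inherits(cohort, "rfp_cohort")) cohort$records else cohort
  if (length(unique(records$treatment_class)) < 2)
    stop("both treatment classes must be present")
  frame <- propensity_frame(records, spec)
  cc <- if (ncol(frame)) stats::complete.cases(frame)
        else rep(TRUE, nrow(records))
  n_dropped <- sum(!cc)
  frame <- frame[cc, , drop = FALSE]
  y <- as.numeric(records$treatment_class[cc] == "A")
  if (min(table(y)) < 2) stop("need >= 2 patients per treatment class")
  x <- if (ncol(frame)) stats::model.matrix(~ ., frame)
       else matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  for (j in seq_len(ncol(x))[-1]) {
    tab <- table(x[, j] > mean(range(x[, j])), y)
    if (nrow(tab) == 2 && any(tab == 0) && length(unique(x[, j])) == 2)
      stop("complete separation on covariate: ", colnames(x)[j])
  }
  fit <- fit_logistic_raw(x, y)
  scores <- rep(NA_real_, nrow(records))
  scores[cc] <- pmin(pmax(fit$fitted, 1e-12), 1 - 1e-12)
  structure(list(coefficients = stats::setNames(fit$coefficients, colnames(x)),
                 vcov = fit$vcov, scores = scores,
                 loglik = fit$loglik, converged = fit$converged,
                 ridge = fit$ridge, n_dropped = n_dropped,
                 treated_fraction = mean(y)),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model:", length(x$coefficients), "terms;",
      sprintf("mean score %.3f", mean(x$scores, na.rm = TRUE)),
      if (x$ridge) "(ridge-stabilised)" else "", "\n")
  if (x$n_dropped) cat("  rows dropped for missing covariates:", x$n_dropped, "\n")
  invisible(x)
}

#' Standardized difference between two groups
#'
#' `(mean1 - mean2) / sqrt((s1^2 + s2^2) / 2)`; for binary (0/1) covariates
#' the variance is `p * (1 - p)`. Undefined (zero pooled variance) returns
#' `NA` with a warning.
#'
#' @param x Numeric or 0/1 covariate values.
#' @param group Two-level grouping vector; the first sorted level is
#'   "group 1".
#' @return A single standardized difference.
#' @export
standardized_difference <- function(x, group) {
  g <- sort(unique(group))
  if (length(g) != 2) stop("grouping must have exactly two levels")
  x1 <- x[group == g[1]]; x2 <- x[group == g[2]]
  binary <- all(x %in% c(0, 1, NA))
  v <- function(z) {
    z <- z[!is.na(z)]
    if (binary) mean(z) * (1 - mean(z)) else stats::var(z)
  }
  denom <- sqrt((v(x1) + v(x2)) / 2)
  if (!is.finite(denom) || denom == 0) {
    warning("zero pooled variance; standardized difference undefined")
    return(NA_real_)
  }
  (mean(x1, na.rm = TRUE) - mean(x2, na.rm = TRUE)) / denom
}

#' Baseline comparison table
#'
#' Per-covariate between-class comparison: chi-square tests (no continuity
#' correction) for categorical covariates, Welch two-sample t-tests for
#' continuous covariates, plus the standardized difference (reported for
#' numeric and binary covariates). Covariates constant in both groups are
#' skipped with `NA` entries.
#'
#' @param cohort An `rfp_cohort` or records data.frame.
#' @param covariates Covariate column names to compare.
#' @return data.frame with columns covariate, type, mean_or_prop_A/B,
#'   p_value, std_diff.
#' @export
baseline_comparison <- function(cohort, covariates) {
  records <- if (inherits(cohort, "rfp_cohort")) cohort$records else cohort
  grp <- records$treatment_class
  rows <- lapply(covariates, function(cv) {
    x <- records[[cv]]
    if (is.null(x)) stop("unknown covariate: ", cv)
    cont <- is.numeric(x) && !all(x %in% c(0, 1, NA))
    if (length(unique(x[!is.na(x)])) < 2) {
      return(data.frame(covariate = cv, type = if (cont) "continuous" else "categorical",
                        mean_or_prop_A = NA_real_, mean_or_prop_B = NA_real_,
                        p_value = NA_real_, std_diff = NA_real_))
    }
    if (cont) {
      p <- stats::t.test(x[grp == "A"], x[grp == "B"])$p.value
      sd_ <- standardized_difference(x, grp)
      mA <- mean(x[grp == "A"], na.rm = TRUE); mB <- mean(x[grp == "B"], na.rm = TRUE)
    } else {
      p <- suppressWarnings(stats::chisq.test(table(grp, x), correct = FALSE)$p.value)
      if (is.numeric(x)) {
        sd_ <- standardized_difference(x, grp)
        mA <- mean(x[grp == "A"], na.rm = TRUE); mB <- mean(x[grp == "B"], na.rm = TRUE)
      } else {
        sd_ <- NA_real_; mA <- NA_real_; mB <- NA_real_
      }
    }
    data.frame(covariate = cv, type = if (cont) "continuous" else "categorical",
               mean_or_prop_A = mA, mean_or_prop_B = mB,
               p_value = p, std_diff = sd_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
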
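#' Unadjusted odds ratio from a 2x2 table
#'
#' `OR = (a * d) / (b * c)` with `a` = treated with outcome, `b` = treated
#' without, `c` = comparator with, `d` = comparator without. The Wald CI is
#' computed on the log scale. A zero cell triggers the Haldane-Anscombe
#' +0.5 correction to every cell, flagged in the result; a row or column
#' that is entirely zero is an error.
#'
#' @param a,b,c,d Non-negative 2x2 cell counts.
#' @param level Confidence level.
#' @return List with `or`, `ci_low`, `ci_high`, `p_value`, `corrected`.
#' @export
unadjusted_or <- function(a, b, c, d, level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("a margin of the 2x2 table is entirely zero; OR undefined")
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  w <- wald_ci_p(log(or), se, level)
  list(or = or, ci_low = exp(w$low), ci_high = exp(w$high),
       p_value = w$p, corrected = corrected)
}

effect_estimate <- function(estimate, ci_low, ci_high, p_value, n,
                            c_statistic = NA_real_, type = "aOR",
                            ridge = FALSE) {
  structure(list(estimate = unname(estimate), ci_low = unname(ci_low),
                 ci_high = unname(ci_high), p_value = unname(p_value),
                 c_statistic = c_statistic, n = n,
                 type = type, ridge = ridge), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d%s%s\n",
              x$type, x$estimate, x$ci_low, x$ci_high, x$p_value, x$n,
              if (!is.na(x$c_statistic))
                sprintf(", c-statistic = %.3f", x$c_statistic) else "",
              if (x$ridge) " [ridge]" else ""))
  invisible(x)
}

#' @export
print.benefit_estimate <- function(x, ...) {
  cat(sprintf("%s %.3f, p = %.4g (within %.3f / outside %.3f)\n",
              if (x$type == "aOR") "ratio of aORs" else "difference of aDeltas",
              x$estimate, x$p_value,
              x$within$estimate, x$outside$estimate))
  invisible(x)
}

records_ty <- function(records, outcome) {
  y <- records[[outcome]]
  keep <- !is.na(y)
  list(y = as.numeric(y[keep]),
       t = as.numeric(records$treatment_class[keep] == "A"),
       keep = keep)
}

#' Propensity-adjusted class effect on a binary outcome
#'
#' Logistic model `outcome ~ treatment + propensity score`; the adjusted
#' odds ratio (aOR) is `exp` of the treatment coefficient, with Wald 95% CI
#' and two-sided p-value. The c-statistic is the area under the ROC curve
#' of the full adjusted model's fitted probabilities against the outcome.
#'
#' @param records Analysis records (rows define the fitting set).
#' @param scores Propensity scores aligned with `records`; `NULL` fits the
#'   unadjusted (treatment-only) model.
#' @param outcome Name of the binary outcome column.
#' @return An `effect_estimate` with `type = "aOR"`.
#' @export
class_effect_binary <- function(records, scores = NULL, outcome = "rfp") {
  d <- records_ty(records, outcome)
  y <- d$y; t <- d$t
  if (length(unique(y)) < 2) stop("outcome is constant; effect undefined")
  if (length(unique(t)) < 2) stop("treatment is constant; effect undefined")
  x <- cbind(`(Intercept)` = 1, treatment = t)
  if (!is.null(scores)) x <- cbind(x, score = scores[d$keep])
  fit <- fit_logistic_raw(x, y)
  se <- sqrt(fit$vcov[2, 2])
  w <- wald_ci_p(fit$coefficients[2], se)
  effect_estimate(exp(fit$coefficients[2]), exp(w$low), exp(w$high), w$p,
                  n = length(y), c_statistic = auc_rank(fit$fitted, y),
                  type = "aOR", ridge = fit$ridge)
}

#' Propensity-adjusted class benefit on a binary outcome
#'
#' Single interaction model
#' `outcome ~ treatment + membership + treatment:membership + score`; the
#' ratio of aORs (within-profile vs outside-profile treatment effect) is
#' `exp` of the interaction coefficient, with a two-sided Wald p-value.
#' Stratified within/outside fits are also reported for display.
#'
#' @param records Analysis records.
#' @param membership Logical profile-membership flags aligned with
#'   `records`.
#' @param scores Propensity scores (or `NULL`).
#' @param outcome Binary outcome column name.
#' @return A `benefit_estimate` with `estimate` = ratio of aORs.
#' @export
class_benefit_binary <- function(records, membership, scores = NULL,
                                 outcome = "rfp") {
  d <- records_ty(records, outcome)
  y <- d$y; t <- d$t; m <- as.numeric(membership)[d$keep]
  if (all(m == 1) || all(m == 0))
    stop("empty stratum: ", if (all(m == 1)) "outside" else "within", " the profile")
  for (s in c(0, 1)) if (length(unique(t[m == s])) < 2)
    stop("a treatment class is missing ",
         if (s == 1) "within" else "outside", " the profile")
  x <- cbind(`(Intercept)` = 1, treatment = t, membership = m,
             interaction = t * m)
  if (!is.null(scores)) x <- cbind(x, score = scores[d$keep])
  fit <- fit_logistic_raw(x, y)
  se <- sqrt(fit$vcov[4, 4])
  w <- wald_ci_p(fit$coefficients[4], se)
  within <- try(class_effect_binary(records[d$keep, ][m == 1, ],
                                    scores[d$keep][m == 1], outcome),
                silent = TRUE)
  outside <- try(class_effect_binary(records[d$keep, ][m == 0, ],
                                     scores[d$keep][m == 0], outcome),
                 silent = TRUE)
  na_est <- effect_estimate(NA_real_, NA_real_, NA_real_, NA_real_, 0L)
  structure(list(estimate = unname(exp(fit$coefficients[4])),
                 ci_low = unname(exp(w$low)), ci_high = unname(exp(w$high)),
                 p_value = unname(w$p),
                 within = if (inherits(within, "try-error")) na_est else within,
                 outside = if (inherits(outside, "try-error")) na_est else outside,
                 type = "aOR", ridge = fit$ridge),
            class = "benefit_estimate")
}

lm_wald <- function(x, y, idx) {
  fit <- stats::lm.fit(x, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  sigma2 <- rss / df
  p <- seq_len(fit$rank)
  piv <- fit$qr$pivot[p]
  R <- fit$qr$qr[p, p, drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- matrix(NA_real_, ncol(x), ncol(x))
  cov[piv, piv] <- chol2inv(R) * sigma2
  se <- sqrt(cov[idx, idx])
  est <- fit$coefficients[idx]
  tval <- est / se
  list(estimate = est, se = se,
       p = 2 * stats::pt(-abs(tval), df),
       ci_low = est - stats::qt(0.975, df) * se,
       ci_high = est + stats::qt(0.975, df) * se)
}

#' Propensity-adjusted class effect on a continuous outcome
#'
#' Gaussian model `outcome ~ treatment + score`; the adjusted mean
#' difference (aDelta) is the treatment coefficient with a t-based 95% CI
#' and two-sided p-value. Rows with a missing outcome are dropped.
#'
#' @inheritParams class_effect_binary
#' @param outcome Continuous outcome column name.
#' @return An `effect_estimate` with `type = "aDelta"`.
#' @export
class_effect_continuous <- function(records, scores = NULL,
                                    outcome = "hba1c_change") {
  d <- records_ty(records, outcome)
  if (length(unique(d$t)) < 2) stop("treatment is constant; effect undefined")
  x <- cbind(`(Intercept)` = 1, treatment = d$t)
  if (!is.null(scores)) x <- cbind(x, score = scores[d$keep])
  w <- lm_wald(x, d$y, 2)
  effect_estimate(w$estimate, w$ci_low, w$ci_high, w$p, n = length(d$y),
                  type = "aDelta")
}

#' Propensity-adjusted class benefit on a continuous outcome
#'
#' Gaussian interaction model; the benefit is the treatment-by-membership
#' interaction coefficient (difference of adjusted mean differences).
#'
#' @inheritParams class_benefit_binary
#' @param outcome Continuous outcome column name.
#' @return A `benefit_estimate` with `type = "aDelta"`.
#' @export
class_benefit_continuous <- function(records, membership, scores = NULL,
                                     outcome = "hba1c_change") {
  d <- records_ty(records, outcome)
  m <- as.numeric(membership)[d$keep]
  if (all(m == 1) || all(m == 0))
    stop("empty stratum: ", if (all(m == 1)) "outside" else "within", " the profile")
  x <- cbind(`(Intercept)` = 1, treatment = d$t, membership = m,
             interaction = d$t * m)
  if (!is.null(scores)) x <- cbind(x, score = scores[d$keep])
  w <- lm_wald(x, d$y, 4)
  within <- try(class_effect_continuous(records[d$keep, ][m == 1, ],
                                        scores[d$keep][m == 1], outcome),
                silent = TRUE)
  outside <- try(class_effect_continuous(records[d$keep, ][m == 0, ],
                                         scores[d$keep][m == 0], outcome),
                 silent = TRUE)
  na_est <- effect_estimate(NA_real_, NA_real_, NA_real_, NA_real_, 0L,
                            type = "aDelta")
  structure(list(estimate = unname(w$estimate), ci_low = unname(w$ci_low),
                 ci_high = unname(w$ci_high), p_value = unname(w$p),
                 within = if (inherits(within, "try-error")) na_est else within,
                 outside = if (inherits(outside, "try-error")) na_est else outside,
                 type = "aDelta", ridge = FALSE),
            class = "benefit_estimate")
}
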
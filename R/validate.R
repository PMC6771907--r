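#' Split configuration
#'
#' @param learning_fraction Fraction of patients allocated to the learning
#'   set (0.70 by default), applied within each treatment class.
#' @param seed Seed for the random allocation.
#' @return A `split_config` list.
#' @export
split_config <- function(learning_fraction = 0.70, seed = 1L) {
  stopifnot(learning_fraction > 0, learning_fraction < 1)
  structure(list(learning_fraction = learning_fraction,
                 seed = as.integer(seed)), class = "split_config")
}

#' Stratified learning/validation split
#'
#' Randomly allocates patients to the learning set within each treatment
#' class. Per-class learning counts are `floor` or `ceiling` of
#' `fraction * n` chosen by largest-remainder rounding against the overall
#' target; the two outputs partition the input. Deterministic given the
#' seed.
#'
#' @param records Analysis records with a `treatment_class` column.
#' @param config A [split_config()].
#' @return List with `learning` and `validation` data.frames (plus
#'   `learning_idx`, the row indices of the learning set).
#' @export
stratified_split <- function(records, config = split_config()) {
  classes <- unique(records$treatment_class)
  if (length(classes) < 2) stop("both treatment classes must be present")
  sizes <- table(records$treatment_class)
  if (any(sizes < 2)) stop("a treatment class has fewer than 2 patients")
  frac <- config$learning_fraction
  ideal <- frac * as.numeric(sizes)
  n_learn <- floor(ideal)
  total_target <- round(frac * nrow(records))
  extra <- total_target - sum(n_learn)
  if (extra > 0) {
    rem_order <- order(ideal - n_learn, decreasing = TRUE)
    n_learn[rem_order[seq_len(extra)]] <- n_learn[rem_order[seq_len(extra)]] + 1
  }
  names(n_learn) <- names(sizes)
  learning_idx <- integer()
  with_stage_seed(config$seed, "split", {
    for (cl in names(sizes)) {
      idx <- which(records$treatment_class == cl)
      learning_idx <- c(learning_idx, sample(idx, n_learn[[cl]]))
    }
  })
  learning_idx <- sort(learning_idx)
  list(learning = records[learning_idx, , drop = FALSE],
       validation = records[-learning_idx, , drop = FALSE],
       learning_idx = learning_idx)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `adj_(i) = min over j >= i of min(1, m * p_(j) / j)` on the sorted
#' p-values, mapped back to input order (ties stable, order-preserving).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  adj <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Re-evaluate screened profiles on the validation set
#'
#' Each profile carried out of screening is evaluated on the validation
#' table with the identical rules; Benjamini-Hochberg adjustment is applied
#' across the carried family, separately for the class-effect and
#' class-benefit p-values. A profile is `validated` when its validation-set
#' threshold flags hold (size, homogeneity, aOR >= threshold with raw
#' p < alpha, benefit ratio >= threshold) and its BH-adjusted class-effect
#' p-value is below `bh_alpha`; requiring the benefit BH p-value as well is
#' configurable (off by default).
#'
#' @param profiles List of `rfp_profile`s or `credibility_report`s from
#'   [screen_profiles()].
#' @param validation Validation table.
#' @param scores Propensity scores aligned with `validation`.
#' @param rules A [screening_rules()].
#' @param bh_alpha BH significance level (0.10).
#' @param require_benefit_bh Also require the benefit BH p < `bh_alpha`.
#' @return List of `validation_result`s: profile, validation
#'   `credibility_report`, `bh_p_class_effect`, `bh_p_class_benefit`,
#'   `validated`, and `reason` when not evaluable.
#' @export
validate_profiles <- function(profiles, validation, scores,
                              rules = screening_rules(), bh_alpha = 0.10,
                              require_benefit_bh = FALSE) {
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "credibility_report")) p$profile else p)
  if (length(profiles) == 0) return(list())
  reports <- lapply(profiles, evaluate_profile, data = validation,
                    scores = scores, rules = rules)
  p_eff <- vapply(reports, function(r)
    if (is.null(r$class_effect)) NA_real_ else r$class_effect$p_value, 0)
  p_ben <- vapply(reports, function(r)
    if (is.null(r$class_benefit)) NA_real_ else r$class_benefit$p_value, 0)
  bh_eff <- rep(NA_real_, length(p_eff))
  bh_ben <- rep(NA_real_, length(p_ben))
  bh_eff[!is.na(p_eff)] <- bh_adjust(p_eff[!is.na(p_eff)])
  bh_ben[!is.na(p_ben)] <- bh_adjust(p_ben[!is.na(p_ben)])
  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    r <- reports[[i]]
    reason <- NULL
    if (r$n == 0) {
      ok <- FALSE; reason <- "no validation-set members"
    } else if (is.null(r$class_effect) || is.null(r$class_benefit)) {
      ok <- FALSE; reason <- r$reason %||% "model undefined on validation set"
    } else {
      ok <- r$pass_flags[["size"]] && r$pass_flags[["homogeneity"]] &&
        r$pass_flags[["effect"]] &&
        r$class_benefit$estimate >= rules$min_benefit_ratio &&
        isTRUE(bh_eff[i] < bh_alpha) &&
        (!require_benefit_bh || isTRUE(bh_ben[i] < bh_alpha))
    }
    out[[i]] <- structure(list(
      profile = profiles[[i]], validation_report = r,
      bh_p_class_effect = bh_eff[i], bh_p_class_benefit = bh_ben[i],
      validated = ok, reason = reason), class = "validation_result")
  }
  out
}

#' @export
print.validation_result <- function(x, ...) {
  r <- x$validation_report
  cat("Profile:", x$profile$label, "-",
      if (x$validated) "VALIDATED" else "not validated",
      if (!is.null(x$reason)) paste0("(", x$reason, ")") else "", "\n")
  if (!is.null(r$class_effect))
    cat(sprintf("  validation aOR = %.2f (p = %.4g, BH p = %.4g)\n",
                r$class_effect$estimate, r$class_effect$p_value,
                x$bh_p_class_effect))
  if (!is.null(r$class_benefit))
    cat(sprintf("  validation ratio = %.2f (p = %.4g, BH p = %.4g)\n",
                r$class_benefit$estimate, r$class_benefit$p_value,
                x$bh_p_class_benefit))
  invisible(x)
}
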
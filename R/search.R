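#' A single profile criterion
#'
#' Continuous variables take `">="` / `"<="` with a numeric bound;
#' categorical (including binary) variables take `"="` with a modality.
#'
#' @param variable Column name.
#' @param operator One of `">="`, `"<="`, `"="`.
#' @param bound Numeric threshold or modality value.
#' @return An `rfp_criterion`.
#' @export
criterion <- function(variable, operator = c(">=", "<=", "="), bound) {
  operator <- match.arg(operator)
  if (operator %in% c(">=", "<=") && !is.numeric(bound))
    stop("bound must be numeric for ", operator)
  structure(list(variable = variable, operator = operator, bound = bound),
            class = "rfp_criterion")
}

format_criterion <- function(cr) {
  b <- if (is.numeric(cr$bound)) format(cr$bound, digits = 4) else cr$bound
  paste(cr$variable, cr$operator, b)
}

#' A candidate patient profile
#'
#' A conjunction of one or two criteria. Two criteria on the same variable
#' with the same operator are rejected; a lower and an upper bound on one
#' continuous variable (an interval) is allowed.
#'
#' @param criteria A [criterion()] or list of 1-2 of them.
#' @param label Optional human-readable label.
#' @return An `rfp_profile`.
#' @export
rfp_profile <- function(criteria, label = NULL) {
  if (inherits(criteria, "rfp_criterion")) criteria <- list(criteria)
  if (length(criteria) < 1 || length(criteria) > 2)
    stop("a profile has 1 or 2 criteria")
  if (length(criteria) == 2 &&
      criteria[[1]]$variable == criteria[[2]]$variable &&
      criteria[[1]]$operator == criteria[[2]]$operator)
    stop("two criteria on the same variable with the same operator")
  label <- label %||% paste(vapply(criteria, format_criterion, ""),
                            collapse = " & ")
  structure(list(criteria = criteria, label = label), class = "rfp_profile")
}

#' @export
print.rfp_profile <- function(x, ...) {
  cat("Profile:", x$label, "\n")
  invisible(x)
}

#' Profile membership
#'
#' @param profile An `rfp_profile` (or `true_profile`).
#' @param data data.frame containing the profile's variables.
#' @return Logical membership vector.
#' @export
profile_membership <- function(profile, data) {
  m <- rep(TRUE, nrow(data))
  for (cr in profile$criteria) {
    x <- data[[cr$variable]]
    if (is.null(x)) stop("profile variable not in data: ", cr$variable)
    m <- m & switch(cr$operator,
                    ">=" = x >= cr$bound,
                    "<=" = x <= cr$bound,
                    "=" = x == cr$bound)
  }
  m & !is.na(m)
}

#' Enumerate candidate criteria from a learning table
#'
#' Continuous variables yield one `">="` and one `"<="` criterion per grid
#' quantile of their learning-set distribution (duplicated bounds removed);
#' categorical and binary variables yield one `"="` criterion per observed
#' modality. Constant variables yield no criteria.
#'
#' @param data Learning-set data.frame.
#' @param variables Variables to search over.
#' @param probs Quantile levels strictly inside (0, 1); deciles by default.
#' @return List of [criterion()] objects in deterministic order.
#' @export
enumerate_criteria <- function(data, variables,
                               probs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(all(probs > 0), all(probs < 1))
  out <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.null(x)) stop("unknown variable: ", v)
    ux <- unique(x[!is.na(x)])
    if (length(ux) < 2) next  # constant variable: nothing to cut
    if (is.numeric(x) && length(ux) > 2) {
      cuts <- unique(unname(stats::quantile(x, probs, na.rm = TRUE, type = 7)))
      for (b in cuts) out[[length(out) + 1]] <- criterion(v, ">=", b)
      for (b in cuts) out[[length(out) + 1]] <- criterion(v, "<=", b)
    } else {
      for (lev in sort(ux)) out[[length(out) + 1]] <- criterion(v, "=", lev)
    }
  }
  out
}

#' Enumerate candidate profiles (singletons and compatible pairs)
#'
#' All single criteria plus all unordered pairs, excluding pairs on the
#' same variable with the same operator (an interval -- `>=` with `<=` on
#' one variable -- is allowed). Output order is deterministic.
#'
#' @param criteria Non-empty list of [criterion()] objects.
#' @return List of [rfp_profile()] objects.
#' @export
enumerate_profiles <- function(criteria) {
  if (length(criteria) == 0) stop("criteria list is empty")
  out <- lapply(criteria, rfp_profile)
  nc <- length(criteria)
  if (nc > 1) {
    for (i in seq_len(nc - 1)) {
      for (j in seq((i + 1), nc)) {
        ci <- criteria[[i]]; cj <- criteria[[j]]
        if (ci$variable == cj$variable && ci$operator == cj$operator) next
        out[[length(out) + 1]] <- rfp_profile(list(ci, cj))
      }
    }
  }
  out
}

#' Screening rules (credibility indicators)
#'
#' The four indicators a profile must pass on the learning set: minimum
#' size (>= 10% of patients), homogeneity of treated-class share (absolute
#' difference vs the whole learning set <= 0.10), class effect (adjusted OR
#' >= 1.5 with p < alpha), and class benefit (ratio of aORs >= 1.5 with
#' p < alpha).
#'
#' @param min_size_fraction,homogeneity_tolerance,min_class_effect_aor,min_benefit_ratio,alpha
#'   Rule parameters.
#' @return A `screening_rules` list.
#' @export
screening_rules <- function(min_size_fraction = 0.10,
                            homogeneity_tolerance = 0.10,
                            min_class_effect_aor = 1.5,
                            min_benefit_ratio = 1.5,
                            alpha = 0.05) {
  stopifnot(min_size_fraction > 0, min_size_fraction <= 1,
            homogeneity_tolerance > 0, homogeneity_tolerance <= 1,
            min_class_effect_aor > 0, min_benefit_ratio > 0,
            alpha > 0, alpha < 1)
  structure(list(min_size_fraction = min_size_fraction,
                 homogeneity_tolerance = homogeneity_tolerance,
                 min_class_effect_aor = min_class_effect_aor,
                 min_benefit_ratio = min_benefit_ratio,
                 alpha = alpha), class = "screening_rules")
}

# Shared evaluation core. `lazy = TRUE` skips the model fits as soon as a
# cheaper indicator fails (used by the batch search); the exported
# evaluate_profile always computes everything it can.
evaluate_core <- function(profile, membership, data, scores, rules,
                          lazy = FALSE, outcome = "rfp") {
  n_all <- nrow(data)
  n <- sum(membership)
  size_fraction <- n / n_all
  t_all <- data$treatment_class == "A"
  treated_share_overall <- mean(t_all)
  treated_share_inside <- if (n > 0) mean(t_all[membership]) else NA_real_
  flags <- c(size = size_fraction >= rules$min_size_fraction,
             homogeneity = isTRUE(abs(treated_share_inside -
                                        treated_share_overall) <=
                                    rules$homogeneity_tolerance),
             effect = FALSE, benefit = FALSE)
  effect <- NULL; benefit <- NULL; reason <- NULL
  if (n == 0) {
    reason <- "profile matches no patients"
  } else {
    do_effect <- !lazy || (flags[["size"]] && flags[["homogeneity"]])
    if (do_effect) {
      effect <- try(class_effect_binary(data[membership, , drop = FALSE],
                                        scores[membership], outcome),
                    silent = TRUE)
      if (inherits(effect, "try-error")) {
        reason <- "class effect undefined"; effect <- NULL
      } else {
        flags[["effect"]] <- effect$estimate >= rules$min_class_effect_aor &&
          effect$p_value < rules$alpha
      }
    }
    do_benefit <- !lazy || (do_effect && flags[["effect"]])
    if (do_benefit) {
      benefit <- try(class_benefit_binary(data, membership, scores, outcome),
                     silent = TRUE)
      if (inherits(benefit, "try-error")) {
        reason <- reason %||% "class benefit undefined"; benefit <- NULL
      } else {
        flags[["benefit"]] <- benefit$estimate >= rules$min_benefit_ratio &&
          benefit$p_value < rules$alpha
      }
    }
  }
  structure(list(profile = profile, n = n, size_fraction = size_fraction,
                 treated_share_inside = treated_share_inside,
                 treated_share_overall = treated_share_overall,
                 class_effect = effect, class_benefit = benefit,
                 pass_flags = flags, overall_pass = all(flags),
                 reason = reason,
                 membership = if (all(flags) || !lazy) membership else NULL),
            class = "credibility_report")
}

#' Evaluate the credibility indicators for one profile
#'
#' Computes membership on the learning table and all four screening
#' indicators (size, treated-share homogeneity, propensity-adjusted class
#' effect, class benefit). `overall_pass` is the conjunction of the four
#' flags, with both model p-values required below `rules$alpha`.
#'
#' @param profile An [rfp_profile()].
#' @param data Learning table with outcomes.
#' @param scores Propensity scores aligned with `data`.
#' @param rules A [screening_rules()].
#' @return A `credibility_report`.
#' @export
evaluate_profile <- function(profile, data, scores,
                             rules = screening_rules()) {
  m <- profile_membership(profile, data)
  evaluate_core(profile, m, data, scores, rules, lazy = FALSE)
}

#' @export
print.credibility_report <- function(x, ...) {
  cat("Profile:", x$profile$label, "\n")
  cat(sprintf("  n = %d (%.1f%%), treated share %.3f vs %.3f overall\n",
              x$n, 100 * x$size_fraction, x$treated_share_inside,
              x$treated_share_overall))
  if (!is.null(x$class_effect))
    cat(sprintf("  class effect aOR = %.2f (p = %.4g)\n",
                x$class_effect$estimate, x$class_effect$p_value))
  if (!is.null(x$class_benefit))
    cat(sprintf("  class benefit ratio = %.2f (p = %.4g)\n",
                x$class_benefit$estimate, x$class_benefit$p_value))
  cat("  flags:", paste(names(x$pass_flags)[x$pass_flags], collapse = ", "),
      "| overall:", x$overall_pass,
      if (!is.null(x$reason)) paste0("(", x$reason, ")") else "", "\n")
  invisible(x)
}

profile_variables <- function(profile)
  unique(vapply(profile$criteria, `[[`, "", "variable"))

#' Screen evaluated profiles
#'
#' Keeps profiles whose four credibility indicators all pass, ranks them by
#' class-benefit p-value (ascending) then benefit ratio (descending),
#' applies optional allow/deny lists on profile variables (the stand-in for
#' the expert clinical-relevance review), and collapses near-duplicate
#' profiles (membership Jaccard > 0.9), keeping the better-ranked one.
#'
#' @param reports List of `credibility_report`s.
#' @param rules A [screening_rules()] (kept for interface symmetry).
#' @param allow_list Optional character vector: profiles may only use these
#'   variables.
#' @param deny_list Optional character vector: profiles using these
#'   variables are dropped.
#' @return The ranked list of passing `credibility_report`s.
#' @export
screen_profiles <- function(reports, rules = screening_rules(),
                            allow_list = NULL, deny_list = NULL) {
  pass <- Filter(function(r) isTRUE(r$overall_pass), reports)
  if (!is.null(allow_list))
    pass <- Filter(function(r) all(profile_variables(r$profile) %in% allow_list), pass)
  if (!is.null(deny_list))
    pass <- Filter(function(r) !any(profile_variables(r$profile) %in% deny_list), pass)
  if (length(pass) == 0) return(list())
  pvals <- vapply(pass, function(r) r$class_benefit$p_value, 0)
  ratios <- vapply(pass, function(r) r$class_benefit$estimate, 0)
  pass <- pass[order(pvals, -ratios)]
  kept <- list()
  for (r in pass) {
    dup <- FALSE
    if (!is.null(r$membership)) {
      for (k in kept) {
        if (is.null(k$membership)) next
        jac <- sum(r$membership & k$membership) /
          sum(r$membership | k$membership)
        if (isTRUE(jac > 0.9)) { dup <- TRUE; break }
      }
    }
    if (!dup) kept[[length(kept) + 1]] <- r
  }
  kept
}

#' Discover benefit profiles on a learning set
#'
#' The search front end: enumerates all candidate criteria over the given
#' variables (quantile grid for continuous, modalities for categorical),
#' forms every 1- and 2-criterion profile, evaluates the four credibility
#' indicators for each, and screens/ranks the passing profiles. The search
#' is exhaustive and fully deterministic.
#'
#' @param data Learning table (analysis records).
#' @param scores Propensity scores aligned with `data`.
#' @param variables Variables to search over.
#' @param rules A [screening_rules()].
#' @param grid Quantile levels for continuous thresholds (deciles by
#'   default).
#' @param allow_list,deny_list Passed to [screen_profiles()].
#' @return A `profile_search` object: ranked passing reports (`screened`),
#'   all evaluated reports (`reports`), counts and settings. Methods:
#'   `print`, `summary`, `predict` (membership of ranked profiles on new
#'   data), `plot`.
#' @examples
#' sim <- simulate_cohort(study_preset(seed = 7, n_patients = 1500))
#' coh <- prepare_cohort(sim$patients, sim$measurements, sim$exposures)
#' ps <- fit_propensity(coh)
#' fit <- discover_profiles(coh$records, ps$scores,
#'                          variables = c("hyperlipidaemia", "antithrombotic"))
#' fit
#' @export
discover_profiles <- function(data, scores, variables,
                              rules = screening_rules(),
                              grid = seq(0.1, 0.9, by = 0.1),
                              allow_list = NULL, deny_list = NULL) {
  criteria <- enumerate_criteria(data, variables, grid)
  if (length(criteria) == 0) stop("no candidate criteria (all variables constant?)")
  profiles <- enumerate_profiles(criteria)
  crit_m <- vapply(criteria, function(cr)
    profile_membership(rfp_profile(list(cr)), data), logical(nrow(data)))
  crit_key <- vapply(criteria, format_criterion, "")
  slim <- data.frame(treatment_class = data$treatment_class, rfp = data$rfp,
                     stringsAsFactors = FALSE)
  reports <- lapply(profiles, function(pr) {
    idx <- match(vapply(pr$criteria, format_criterion, ""), crit_key)
    m <- if (length(idx) == 1) crit_m[, idx] else crit_m[, idx[1]] & crit_m[, idx[2]]
    evaluate_core(pr, m, slim, scores, rules, lazy = TRUE)
  })
  screened <- screen_profiles(reports, rules, allow_list, deny_list)
  structure(list(screened = screened, reports = reports,
                 n_evaluated = length(reports),
                 n_passed = sum(vapply(reports, `[[`, TRUE, "overall_pass")),
                 rules = rules, variables = variables, grid = grid,
                 n = nrow(data), call = match.call()),
            class = "profile_search")
}

#' @export
print.profile_search <- function(x, ...) {
  cat("Profile search:", x$n_evaluated, "profiles evaluated on",
      x$n, "patients;", x$n_passed, "passed screening,",
      length(x$screened), "retained after ranking/dedup\n")
  for (i in seq_along(x$screened)) {
    r <- x$screened[[i]]
    cat(sprintf("  %d. %s  [n=%d (%.0f%%), aOR=%.2f, ratio=%.2f, p=%.4g]\n",
                i, r$profile$label, r$n, 100 * r$size_fraction,
                r$class_effect$estimate, r$class_benefit$estimate,
                r$class_benefit$p_value))
  }
  invisible(x)
}

#' @export
summary.profile_search <- function(object, ...) {
  df <- do.call(rbind, lapply(object$reports, function(r) data.frame(
    profile = r$profile$label, n = r$n, size_fraction = r$size_fraction,
    treated_share_inside = r$treated_share_inside,
    aor = if (is.null(r$class_effect)) NA_real_ else r$class_effect$estimate,
    aor_p = if (is.null(r$class_effect)) NA_real_ else r$class_effect$p_value,
    ratio = if (is.null(r$class_benefit)) NA_real_ else r$class_benefit$estimate,
    ratio_p = if (is.null(r$class_benefit)) NA_real_ else r$class_benefit$p_value,
    pass = r$overall_pass, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' @export
predict.profile_search <- function(object, newdata, ...) {
  out <- vapply(object$screened, function(r)
    profile_membership(r$profile, newdata), logical(nrow(newdata)))
  colnames(out) <- vapply(object$screened, function(r) r$profile$label, "")
  out
}

#' @export
plot.profile_search <- function(x, ...) {
  if (length(x$screened) == 0) {
    graphics::plot.new()
    graphics::title("No profiles passed screening")
    return(invisible(x))
  }
  ratios <- vapply(x$screened, function(r) r$class_benefit$estimate, 0)
  labels <- vapply(x$screened, function(r) r$profile$label, "")
  graphics::dotchart(rev(ratios), labels = rev(labels),
                     xlab = "class benefit (ratio of aORs)", ...)
  graphics::abline(v = x$rules$min_benefit_ratio, lty = 2)
  invisible(x)
}
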
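# Independent oracles and small fixture builders used across the suite.

# Brute-force maximum-likelihood logistic fit (BFGS with analytic gradient),
# independent of the package's IRLS path.
oracle_logistic <- function(x, y) {
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) -drop(crossprod(x, y - plogis(drop(x %*% b))))
  fit <- optim(rep(0, ncol(x)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Brute-force least squares via the normal equations.
oracle_linear <- function(x, y) drop(solve(crossprod(x), crossprod(x, y)))

# Brute-force Benjamini-Hochberg step-up straight from the definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j) on sorted p-values, by
# explicit double loop (no cummin shortcut).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- best
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# A small analysis-records table with direct control over treatment,
# outcome, and one covariate (for effect-model unit tests).
make_records <- function(t, y, hba1c_change = NULL, extra = NULL) {
  df <- data.frame(treatment_class = ifelse(t == 1, "A", "B"), rfp = y,
                   stringsAsFactors = FALSE)
  if (!is.null(hba1c_change)) df$hba1c_change <- hba1c_change
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

# A tiny simulation config over a handful of covariates, for generator and
# round-trip tests that do not need the full study preset.
tiny_config <- function(n = 1000, seed = 1, ...) {
  sim_config(
    n_patients = n,
    covariate_specs = list(
      cov_spec("age", "continuous", mean = 60, sd = 10, min = 18, max = 90),
      cov_spec("sex", "categorical", levels = c("male", "female"),
               probs = c(0.5, 0.5)),
      cov_spec("egfr", "continuous", mean = 75, sd = 15, min = 25, max = 130),
      cov_spec("hba1c", "continuous", mean = 7.5, sd = 1, min = 5.5, max = 12),
      cov_spec("flag", "binary", prevalence = 0.5)),
    seed = seed, ...)
}

truth_label <- "hyperlipidaemia = 0 & antithrombotic = 1"
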
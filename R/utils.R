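# Internal helpers shared across modules.

# Derive a per-stage RNG seed from the master seed so that changing one
# stage's parameters never perturbs another stage's draws. Kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(covariates = 11L, treatment = 23L, outcomes = 37L,
               measurements = 53L, ineligible = 71L, split = 89L)
  if (!stage %in% names(offsets)) stop("unknown rng stage: ", stage)
  as.integer((as.numeric(seed) * 1000003 + offsets[[stage]]) %% 2147483629)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

# Area under the ROC curve via the rank (Mann-Whitney) identity.
auc_rank <- function(score, outcome) {
  y <- as.integer(outcome)
  n1 <- as.numeric(sum(y == 1L)); n0 <- as.numeric(sum(y == 0L))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Maximum-likelihood logistic fit on a prebuilt design matrix, with Wald
# covariance, and a ridge-stabilised fallback (penalty lambda) when the
# unpenalised fit fails to converge or separates. Returns coefficients,
# their covariance, fitted probabilities and a 'ridge' flag.
fit_logistic_raw <- function(x, y, lambda = 1e-4) {
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  sep <- any(abs(fit$coefficients) > 15, na.rm = TRUE) ||
    any(is.na(fit$coefficients)) || !fit$converged
  if (!sep) {
    p <- seq_len(fit$rank)
    piv <- fit$qr$pivot[p]
    R <- fit$qr$qr[p, p, drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- matrix(NA_real_, ncol(x), ncol(x))
    cov[piv, piv] <- chol2inv(R)
    list(coefficients = fit$coefficients, vcov = cov,
         fitted = fit$fitted.values, loglik = -fit$deviance / 2,
         converged = TRUE, ridge = FALSE)
  } else {
    ridge_logistic(x, y, lambda = lambda)
  }
}

# Penalised IRLS with Wald covariance from the penalised information matrix.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  p <- ncol(x)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  pen[1, 1] <- 0  # never penalise the intercept
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- crossprod(x, w * x) + pen
    beta_new <- drop(solve(xtw, crossprod(x, w * z)))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(x, w * x) + pen
  ll <- sum(y * eta - log1p(exp(eta)))
  list(coefficients = beta, vcov = solve(info), fitted = mu,
       loglik = ll, converged = TRUE, ridge = TRUE)
}

wald_ci_p <- function(est, se, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(low = est - zq * se, high = est + zq * se,
       p = 2 * stats::pnorm(-abs(est / se)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
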
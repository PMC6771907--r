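test_that("unadjusted odds ratio follows ad/bc with Haldane-Anscombe correction", {
  expect_equal(unadjusted_or(10, 10, 10, 10)$or, 1)
  expect_equal(unadjusted_or(20, 10, 10, 20)$or, 4)
  set.seed(21)
  for (i in 1:50) {
    k <- sample(1:40, 4, replace = TRUE)
    expect_equal(unadjusted_or(k[1], k[2], k[3], k[4])$or,
                 (k[1] * k[4]) / (k[2] * k[3]), tolerance = 1e-12)
  }
  cz <- unadjusted_or(1, 0, 1, 1)
  expect_true(cz$corrected)
  expect_equal(cz$or, (1.5 * 1.5) / (0.5 * 1.5))  # 3.0
  expect_error(unadjusted_or(0, 0, 5, 5), "zero")
})

test_that("logistic and Gaussian fits agree with brute-force likelihood maximization", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    t <- rbinom(n, 1, 0.5)
    s <- runif(n, 0.1, 0.9)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * t + 0.5 * s))
    if (length(unique(y)) < 2 || length(unique(t)) < 2) next
    x <- cbind(1, t, s)
    ref <- oracle_logistic(x, y)
    est <- class_effect_binary(make_records(t, y), s)
    expect_equal(log(est$estimate), ref[2], tolerance = 1e-4)
    yc <- rnorm(n, 0.2 * t - 0.4 * s, 0.5)
    refc <- oracle_linear(x, yc)
    estc <- class_effect_continuous(make_records(t, y, hba1c_change = yc), s)
    expect_equal(estc$estimate, unname(refc[2]), tolerance = 1e-6)
  }
})

test_that("score-free adjusted model collapses to the unadjusted 2x2 odds ratio", {
  set.seed(23)
  for (i in 1:5) {
    t <- rbinom(400, 1, 0.4); y <- rbinom(400, 1, 0.3 + 0.2 * t)
    est <- class_effect_binary(make_records(t, y), scores = NULL)
    tab <- table(factor(t, c(1, 0)), factor(y, c(1, 0)))
    u <- unadjusted_or(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(log(est$estimate), log(u$or), tolerance = 1e-6)
  }
})

test_that("adjustment removes generator confounding (null treatment effect)", {
  set.seed(24)
  n <- 1e5
  x <- rnorm(n)
  a <- uniroot(function(a) mean(plogis(a + x)) - 0.4, c(-6, 6))$root
  t <- rbinom(n, 1, plogis(a + x))
  b <- uniroot(function(b) mean(plogis(b + x)) - 0.4, c(-6, 6))$root
  y <- rbinom(n, 1, plogis(b + x))
  rec <- make_records(t, y, extra = data.frame(x = x))
  ps <- fit_propensity(rec, propensity_spec(terms = "x"))
  unadj <- class_effect_binary(rec, NULL)
  expect_gt(unadj$ci_low, 1)  # confounding visible without adjustment
  adj <- class_effect_binary(rec, ps$scores)
  expect_equal(adj$estimate, 1, tolerance = 0.1)
})

test_that("a known treatment effect is recovered and the c-statistic is calibrated", {
  set.seed(25)
  n <- 1e5
  t <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(qlogis(0.35) + log(2.5) * t))
  est <- class_effect_binary(make_records(t, y), runif(n))
  expect_equal(est$estimate, 2.5, tolerance = 0.06)
  # outcome independent of everything: c-statistic 0.5
  y0 <- rbinom(1e4, 1, 0.4)
  est0 <- class_effect_binary(make_records(rbinom(1e4, 1, 0.5), y0),
                              runif(1e4))
  expect_equal(est0$c_statistic, 0.5, tolerance = 0.02)
})

test_that("c-statistic matches an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  t <- rbinom(300, 1, 0.5); s <- runif(300)
  y <- rbinom(300, 1, plogis(-0.5 + t + s))
  est <- class_effect_binary(make_records(t, y), s)
  fit <- glm(y ~ t + s, family = binomial)
  ref <- as.numeric(pROC::auc(pROC::roc(y, fitted(fit), quiet = TRUE)))
  expect_equal(est$c_statistic, ref, tolerance = 1e-9)
})

test_that("interaction model estimates the benefit ratio and is symmetric", {
  set.seed(27)
  n <- 1e5
  m <- rbinom(n, 1, 0.3)
  t <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.2 * t + log(2.0) * t * m))
  rec <- make_records(t, y)
  s <- runif(n)
  ben <- class_benefit_binary(rec, m == 1, s)
  expect_equal(ben$estimate, 2.0, tolerance = 0.08)  # 2.0 +/- 0.2
  # relabelling membership to its complement inverts the ratio exactly
  ben2 <- class_benefit_binary(rec, m == 0, s)
  expect_equal(log(ben2$estimate), -log(ben$estimate), tolerance = 1e-6)
  # uniform effect: ratio 1
  y3 <- rbinom(n, 1, plogis(-0.5 + 0.4 * t))
  ben3 <- class_benefit_binary(make_records(t, y3), m == 1, s)
  expect_equal(ben3$estimate, 1.0, tolerance = 0.1)
})

test_that("benefit model errors name empty or degenerate strata", {
  rec <- make_records(rep(c(1, 0), 20), rbinom(40, 1, 0.5))
  expect_error(class_benefit_binary(rec, rep(TRUE, 40), NULL), "outside")
  expect_error(class_benefit_binary(rec, rep(FALSE, 40), NULL), "within")
  m <- rep(c(TRUE, FALSE), each = 20)
  rec2 <- make_records(c(rep(1, 20), rep(c(1, 0), 10)), rbinom(40, 1, 0.5))
  expect_error(class_benefit_binary(rec2, m, NULL), "missing within")
})

test_that("continuous effect models honour location invariance and known shifts", {
  set.seed(28)
  n <- 1e5
  t <- rbinom(n, 1, 0.3); s <- runif(n)
  y0 <- rnorm(n, -0.4 + 0 * t, 0.8)
  est0 <- class_effect_continuous(make_records(t, 1, hba1c_change = y0), s)
  expect_equal(est0$estimate, 0, tolerance = 0.03)
  y1 <- rnorm(n, -0.4 - 0.3 * t, 0.8)
  rec1 <- make_records(t, 1, hba1c_change = y1)
  est1 <- class_effect_continuous(rec1, s)
  expect_lt(abs(est1$estimate - (-0.30)), 0.03)
  rec2 <- rec1; rec2$hba1c_change <- rec2$hba1c_change + 100
  est2 <- class_effect_continuous(rec2, s)
  expect_equal(est2$estimate, est1$estimate, tolerance = 1e-9)
  # continuous benefit: interaction recovered
  m <- rbinom(n, 1, 0.4)
  y3 <- rnorm(n, 0.1 * t - 0.25 * t * m, 0.8)
  ben <- class_benefit_continuous(make_records(t, 1, hba1c_change = y3),
                                  m == 1, s)
  expect_lt(abs(ben$estimate - (-0.25)), 0.03)
})

test_that("95% Wald CI for a null treatment aOR has nominal coverage", {
  set.seed(29)
  cover <- vapply(1:500, function(i) {
    t <- rbinom(400, 1, 0.4)
    y <- rbinom(400, 1, 0.4)
    est <- tryCatch(class_effect_binary(make_records(t, y), NULL),
                    error = function(e) NULL)
    if (is.null(est)) return(NA)
    est$ci_low <= 1 && est$ci_high >= 1
  }, TRUE)
  expect_equal(mean(cover, na.rm = TRUE), 0.95, tolerance = 0.031)
})
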
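search_table <- function(n = 400, seed = 1) {
  set.seed(seed)
  data.frame(treatment_class = sample(c("A", "B"), n, TRUE, c(0.3, 0.7)),
             rfp = rbinom(n, 1, 0.4),
             cont = rnorm(n), bin = rbinom(n, 1, 0.5),
             cat = sample(c("x", "y", "z"), n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("criterion enumeration follows variable types and the quantile grid", {
  tab <- search_table(500)
  # binary variable -> exactly 2 modality criteria
  cb <- enumerate_criteria(tab, "bin")
  expect_length(cb, 2)
  expect_true(all(vapply(cb, `[[`, "", "operator") == "="))
  # categorical with 3 modalities -> 3
  expect_length(enumerate_criteria(tab, "cat"), 3)
  # continuous with 9 decile cuts -> 18 criteria (2 operators x 9 cuts)
  cc <- enumerate_criteria(tab, "cont")
  expect_length(cc, 18)
  expect_setequal(unique(vapply(cc, `[[`, "", "operator")), c(">=", "<="))
  bounds <- vapply(Filter(function(x) x$operator == ">=", cc), `[[`, 0, "bound")
  expect_equal(sort(bounds),
               unname(quantile(tab$cont, seq(0.1, 0.9, 0.1))),
               tolerance = 1e-12)
  # constant variable -> no criteria
  tab$const <- 5
  expect_length(enumerate_criteria(tab, "const"), 0)
})

test_that("profile enumeration emits singletons plus compatible pairs", {
  crits <- list(criterion("a", ">=", 1), criterion("b", "<=", 2),
                criterion("c", "=", "x"))
  profs <- enumerate_profiles(crits)
  expect_length(profs, 6)  # 3 singletons + 3 pairs on distinct variables
  # same variable, same operator: pair suppressed
  crits2 <- list(criterion("a", ">=", 1), criterion("a", ">=", 2))
  expect_length(enumerate_profiles(crits2), 2)
  # same variable, opposite operators: interval allowed
  crits3 <- list(criterion("a", ">=", 1), criterion("a", "<=", 2))
  expect_length(enumerate_profiles(crits3), 3)
  expect_error(enumerate_profiles(list()), "empty")
  # exhaustiveness: closed-form count on the full generated criteria set
  tab <- search_table(300)
  crits4 <- enumerate_criteria(tab, c("cont", "bin", "cat"))
  n_cont <- 18; n_bin <- 2; n_cat <- 3
  total <- n_cont + n_bin + n_cat
  same_var_same_op <- 2 * choose(9, 2) + choose(n_bin, 2) + choose(n_cat, 2)
  expected <- total + choose(total, 2) - same_var_same_op
  expect_length(enumerate_profiles(crits4), expected)
})

test_that("membership is monotone in threshold tightening", {
  tab <- search_table(600, seed = 3)
  cuts <- quantile(tab$cont, c(0.3, 0.5, 0.7))
  for (i in 1:2) {
    loose <- profile_membership(rfp_profile(criterion("cont", ">=", cuts[i])), tab)
    tight <- profile_membership(rfp_profile(criterion("cont", ">=", cuts[i + 1])), tab)
    expect_true(all(loose[tight]))  # tight subset of loose
    expect_lte(sum(tight), sum(loose))
  }
})

test_that("profile evaluation applies the four credibility indicators", {
  set.seed(4)
  n <- 2000
  tab <- data.frame(
    treatment_class = sample(c("A", "B"), n, TRUE, c(0.19, 0.81)),
    bin = rbinom(n, 1, 0.5), stringsAsFactors = FALSE)
  tab$rfp <- rbinom(n, 1, plogis(-0.4 + log(3) * (tab$treatment_class == "A") * tab$bin))
  scores <- rep(0.19, n)
  rules <- screening_rules()
  # the whole table: complement empty, benefit undefined, overall fail
  whole <- evaluate_profile(rfp_profile(criterion("bin", ">=", -1)), tab,
                            scores, rules)
  expect_equal(whole$size_fraction, 1)
  expect_false(whole$overall_pass)
  expect_null(whole$class_benefit)
  # an all-treated subgroup violates homogeneity (|1 - 0.19| > 0.10)
  tab2 <- tab; tab2$allA <- as.integer(tab2$treatment_class == "A")
  r2 <- evaluate_profile(rfp_profile(criterion("allA", "=", 1)), tab2,
                         scores, rules)
  expect_false(r2$pass_flags[["homogeneity"]])
  # a genuine benefit subgroup passes all four
  r3 <- evaluate_profile(rfp_profile(criterion("bin", "=", 1)), tab,
                         scores, rules)
  expect_true(r3$overall_pass)
  # empty profile: explicit reason
  tab$neg <- 0
  r4 <- evaluate_profile(rfp_profile(criterion("neg", "=", 1)), tab, scores, rules)
  expect_false(r4$overall_pass)
  expect_match(r4$reason, "no patients")
})

test_that("screening ranks by benefit p-value and collapses near-duplicates", {
  set.seed(5)
  n <- 3000
  tab <- data.frame(
    treatment_class = sample(c("A", "B"), n, TRUE, c(0.3, 0.7)),
    bin = rbinom(n, 1, 0.4), stringsAsFactors = FALSE)
  tab$bin_copy <- tab$bin
  tab$rfp <- rbinom(n, 1, plogis(-0.4 + log(2.5) * (tab$treatment_class == "A") * tab$bin))
  scores <- rep(0.3, n)
  fit <- discover_profiles(tab, scores, c("bin", "bin_copy"))
  # identical membership on bin and bin_copy: only one survivor
  labs <- vapply(fit$screened, function(r) r$profile$label, "")
  expect_length(grep("= 1", labs), 1)
  # ranked output deterministic under rerun
  fit2 <- discover_profiles(tab, scores, c("bin", "bin_copy"))
  expect_identical(vapply(fit2$screened, function(r) r$profile$label, ""), labs)
  # no passing profile -> empty list
  expect_length(screen_profiles(list()), 0)
  # allow/deny lists filter on profile variables
  s_allow <- screen_profiles(fit$reports, fit$rules, allow_list = "bin_copy")
  expect_true(all(vapply(s_allow, function(r)
    all(vapply(r$profile$criteria, `[[`, "", "variable") == "bin_copy"), TRUE)))
  s_deny <- screen_profiles(fit$reports, fit$rules,
                            deny_list = c("bin", "bin_copy"))
  expect_length(s_deny, 0)
})

test_that("an implanted profile passes all four indicators in nearly every seed", {
  passes <- vapply(1:20, function(s) {
    cfg <- tiny_config(
      n = 10000, seed = s, treated_fraction_target = 0.3,
      implanted_profiles = list(true_profile(criterion("flag", "=", 1),
                                             log(2.5))))
    cov <- draw_covariates(cfg)
    trt <- assign_treatment(cov, cfg)
    out <- generate_outcomes(cov, trt, cfg)
    tab <- data.frame(treatment_class = trt, rfp = out$rfp, flag = cov$flag)
    rep <- evaluate_profile(rfp_profile(criterion("flag", "=", 1)), tab,
                            rep(0.3, nrow(tab)))
    rep$overall_pass
  }, TRUE)
  expect_gte(mean(passes), 0.95)
})

test_that("profile construction rejects invalid criterion combinations", {
  expect_error(criterion("x", ">=", "text"), "numeric")
  expect_error(rfp_profile(list(criterion("x", ">=", 1),
                                criterion("x", ">=", 2))), "same operator")
  expect_error(rfp_profile(list(criterion("x", ">=", 1),
                                criterion("y", "<=", 2),
                                criterion("z", "=", "a"))), "1 or 2")
})
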
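test_that("covariate draws match their specified distributions", {
  cfg <- tiny_config(n = 1e5)
  cov <- draw_covariates(cfg)
  expect_equal(nrow(cov), 1e5)
  expect_lt(abs(mean(cov$flag) - 0.5), 0.01)
  # truncation bounds respected; mean of a wide-bound normal near mu
  expect_true(all(cov$egfr >= 25 & cov$egfr <= 130))
  # CLT bound: sd 15/sqrt(1e5) ~ 0.047; 4 sigma plus small truncation shift
  expect_lt(abs(mean(cov$egfr) - 75), 0.3)
  expect_error(
    draw_covariates(sim_config(10, covariate_specs = list(
      cov_spec("x", "continuous", dist = "cauchyish")))),
    "unknown distribution")
})

test_that("the generator is deterministic and stage streams are isolated", {
  cfg <- tiny_config(n = 500, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$exposures, s2$exposures)
  # changing the outcome model must not perturb the covariate draws
  cfg2 <- tiny_config(n = 500, seed = 77, base_treatment_log_or = 1)
  s3 <- simulate_cohort(cfg2)
  expect_identical(s1$patients[c("age", "sex", "egfr")],
                   s3$patients[c("age", "sex", "egfr")])
})

test_that("treatment assignment hits the marginal target and encodes confounding", {
  cfg <- tiny_config(n = 1e5, treated_fraction_target = 0.19)
  cov <- draw_covariates(cfg)
  trt <- assign_treatment(cov, cfg)  # no confounding coefficients
  expect_lt(abs(mean(trt == "A") - 0.19), 0.01)

  cfg2 <- tiny_config(n = 1e5, treated_fraction_target = 0.5,
                      confounding_coefficients = c(egfr = 0.05))
  trt2 <- assign_treatment(cov, cfg2)
  expect_gt(mean(cov$egfr[trt2 == "A"]), mean(cov$egfr[trt2 == "B"]))
  # logistic-regression oracle recovers the assignment coefficient
  b <- glm(I(trt2 == "A") ~ egfr, data = cov, family = binomial)
  expect_equal(unname(coef(b)["egfr"]), 0.05, tolerance = 0.1)
})

test_that("a unit coefficient on a standard-normal covariate is recovered", {
  cfg <- sim_config(
    n_patients = 1e5, treated_fraction_target = 0.5,
    covariate_specs = list(cov_spec("x", "continuous", mean = 0, sd = 1)),
    confounding_coefficients = c(x = 1.0), seed = 5)
  cov <- draw_covariates(cfg)
  trt <- assign_treatment(cov, cfg)
  fit <- glm(I(trt == "A") ~ x, data = cov, family = binomial)
  expect_equal(unname(coef(fit)["x"]), 1.0, tolerance = 0.05)
})

test_that("outcome generation calibrates implanted effects and the HbA1c null", {
  cfg <- tiny_config(
    n = 1e5, seed = 9, treated_fraction_target = 0.5,
    implanted_profiles = list(
      true_profile(criterion("flag", "=", 1), log(2.5))))
  cov <- draw_covariates(cfg)
  trt <- assign_treatment(cov, cfg)
  out <- generate_outcomes(cov, trt, cfg)
  # within-profile empirical OR from the 2x2 contingency oracle
  m <- cov$flag == 1
  tab <- table(trt[m], out$rfp[m])
  or <- (tab["A", "1"] * tab["B", "0"]) / (tab["A", "0"] * tab["B", "1"])
  expect_equal(unname(or), 2.5, tolerance = 0.08)  # 2.5 +/- 0.2
  # no treatment difference in HbA1c change when hba1c_effect = 0
  expect_lt(abs(mean(out$hba1c_change[trt == "A"]) -
                  mean(out$hba1c_change[trt == "B"])), 0.02)
  # marginal outcome rate matches the calibrated intercept target
  expect_lt(abs(mean(out$rfp) - cfg$rfp_target_rate), 0.01)
})

test_that("null outcome model shows no treatment association", {
  pvals <- vapply(1:40, function(s) {
    cfg <- tiny_config(n = 2000, seed = s, treated_fraction_target = 0.3)
    cov <- draw_covariates(cfg)
    trt <- assign_treatment(cov, cfg)
    out <- generate_outcomes(cov, trt, cfg)
    suppressWarnings(chisq.test(table(trt, out$rfp), correct = FALSE)$p.value)
  }, 0)
  # p-values roughly uniform under the null; KS check at a loose level
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("emitted raw tables are consistent with the generator's intent", {
  cfg <- tiny_config(n = 300, seed = 21)
  sim <- simulate_cohort(cfg)
  # back-solved creatinine reproduces the intended eGFR exactly
  base_cr <- sim$measurements[sim$measurements$analyte == "creatinine" &
                                sim$measurements$date >= -60, ]
  i <- match(sim$patients$patient_id, base_cr$patient_id)
  egfr <- compute_egfr(base_cr$value[i], sim$patients$age, sim$patients$sex)
  expect_equal(egfr, sim$truth$baseline_egfr, tolerance = 1e-9)
  # ineligible fraction 0: every patient passes eligibility
  coh <- prepare_cohort(sim$patients, sim$measurements, sim$exposures)
  expect_equal(sum(coh$attrition$n_excluded), 0)
  expect_equal(nrow(coh$records), 300)
})

test_that("the ineligible fraction produces the expected attrition volume", {
  cfg <- tiny_config(n = 5000, seed = 31, ineligible_fraction = 0.2)
  sim <- simulate_cohort(cfg)
  n_bad <- sum(sim$truth$violation != "none")
  expect_lt(abs(n_bad - 1000), 70)  # binomial noise around 0.2 * 5000
  coh <- prepare_cohort(sim$patients, sim$measurements, sim$exposures)
  expect_equal(sum(coh$attrition$n_excluded), n_bad)
  expect_equal(nrow(coh$records), 5000 - n_bad)
})

test_that("a JSON/YAML config file round-trips into an equivalent simulation", {
  path <- file.path(tempdir(), "sim_cfg.json")
  jsonlite::write_json(list(
    n_patients = 250, seed = 9, treated_fraction_target = 0.3,
    base_treatment_log_or = 0.1,
    implanted_profiles = list(list(
      criteria = list(list(variable = "hyperlipidaemia", operator = "=",
                           bound = 0)),
      extra_treatment_log_or = log(2)))),
    path, auto_unbox = TRUE, digits = NA)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_patients, 250L)
  expect_equal(cfg$treated_fraction_target, 0.3)
  expect_length(cfg$implanted_profiles, 1)
  ref <- study_preset(seed = 9, n_patients = 250)
  ref$treated_fraction_target <- 0.3
  ref$base_treatment_log_or <- 0.1
  ref$implanted_profiles <- list(true_profile(
    criterion("hyperlipidaemia", "=", 0), log(2)))
  expect_identical(simulate_cohort(cfg)$patients,
                   simulate_cohort(ref)$patients)
  writeLines("n_patients: 99\nnot_a_field: 1", sub("json$", "yaml", path))
  skip_if_not_installed("yaml")
  expect_error(read_sim_config(sub("json$", "yaml", path)), "unknown config")
  unlink(path)
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(tiny_config(n = 100, treated_fraction_target = 1.2))
  expect_error(tiny_config(n = 100,
                           confounding_coefficients = c(nope = 1)),
               "unknown covariate")
  expect_error(tiny_config(n = 100, implanted_profiles = list(
    true_profile(criterion("nope", "=", 1), 0.5))), "unknown covariate")
  expect_error(true_profile(list(), 0.5), "1 or 2")
})
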
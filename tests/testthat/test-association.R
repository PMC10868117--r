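# Simulated covariate tables for the mixed-model wrappers: patients with
# repeated admissions, an institution indicator constant within patient.
sim_glmm_data <- function(n_patients = 600, k = 3, beta_inst = log(2),
                          intercept = -1, re_sd = 1, seed = 1,
                          gaussian = FALSE) {
  set.seed(seed)
  inst <- rep(rbinom(n_patients, 1, 0.5), each = k)
  b <- rep(rnorm(n_patients, 0, re_sd), each = k)
  eta <- intercept + beta_inst * inst + b
  data.frame(
    patient_id = rep(sprintf("p%04d", seq_len(n_patients)), each = k),
    institution = factor(ifelse(inst == 1, "site_b", "site_a")),
    y = if (gaussian) eta + rnorm(n_patients * k)
        else rbinom(n_patients * k, 1, plogis(eta)))
}

test_that("wald intervals use the inverse-normal multiplier", {
  # z at the 99.9% level
  expect_equal(unname(wald_ci(0, 1, 0.999)[1, "high"]), 3.2905,
               tolerance = 1e-4)
  ci <- wald_ci(0, 2, 0.999)
  expect_equal(ci[1, "low"], -ci[1, "high"], ignore_attr = TRUE)
  expect_true(all(exp(ci[, "low"]) < 1 & exp(ci[, "high"]) > 1))
  # CI nesting across levels and the se -> 0 limit
  ci95 <- wald_ci(1.2, 0.3, 0.95)
  ci999 <- wald_ci(1.2, 0.3, 0.999)
  expect_lt(ci999[1, "low"], ci95[1, "low"])
  expect_gt(ci999[1, "high"], ci95[1, "high"])
  expect_equal(unname(wald_ci(1.2, 0, 0.999)), c(1.2, 1.2),
               ignore_attr = TRUE)
})

test_that("zero-variance data reduce the mixed fits to glm and lm", {
  # With no true between-patient variance the variance estimate lands on
  # the boundary for a substantial share of finite datasets; whenever it
  # does, the fixed effects must coincide with the plain logistic MLE.
  boundary <- 0L
  for (s in 1:4) {
    d <- sim_glmm_data(n_patients = 400, re_sd = 0, seed = s)
    f <- fit_random_intercept_logistic(d, "y", fixed = "institution")
    if (f$re_sd < 1e-4) {
      boundary <- boundary + 1L
      g <- glm(y ~ institution, binomial, d)
      expect_lt(max(abs(coef(f) - coef(g))), 1e-4)
      expect_true(f$singular)
    }
  }
  expect_gte(boundary, 1L)

  dg <- sim_glmm_data(re_sd = 0, seed = 4, gaussian = TRUE)
  fl <- fit_random_intercept_linear(dg, "y", fixed = "institution")
  ol <- lm(y ~ institution, dg)
  expect_lt(max(abs(coef(fl) - coef(ol))), 1e-4)
})

test_that("the institution effect is recovered and stable in quadrature nodes", {
  d <- sim_glmm_data(n_patients = 1200, seed = 5)
  f15 <- fit_random_intercept_logistic(d, "y", fixed = "institution",
                                       nAGQ = 15)
  f30 <- fit_random_intercept_logistic(d, "y", fixed = "institution",
                                       nAGQ = 30)
  i <- grep("institution", f15$coefficients$term)
  # doubling the nodes moves the log-OR by < 1e-3
  expect_lt(abs(f15$coefficients$estimate[i] -
                  f30$coefficients$estimate[i]), 1e-3)
  ci <- wald_ci(f15$coefficients$estimate[i], f15$coefficients$se[i])
  expect_true(ci[1, "low"] <= log(2) && log(2) <= ci[1, "high"])
  expect_gt(f15$re_sd, 0.5)

  # the independent quadrature evaluator reproduces the fitted
  # log-likelihood and is itself node-stable at the optimum
  X <- model.matrix(~ institution, d)
  ll15 <- agq_loglik(d$y, X, d$patient_id, coef(f15), f15$re_sd, 15)
  ll30 <- agq_loglik(d$y, X, d$patient_id, coef(f15), f15$re_sd, 30)
  expect_equal(ll15, f15$loglik, tolerance = 1e-6)
  expect_lt(abs(ll30 - ll15), 1e-4)
})

test_that("estimates are invariant under permutation of patient identifiers", {
  d <- sim_glmm_data(n_patients = 300, seed = 6)
  perm <- setNames(sample(unique(d$patient_id)), unique(d$patient_id))
  d2 <- d
  d2$patient_id <- unname(perm[d$patient_id])
  f1 <- fit_random_intercept_logistic(d, "y", fixed = "institution")
  f2 <- fit_random_intercept_logistic(d2, "y", fixed = "institution")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$re_sd, f2$re_sd, tolerance = 1e-5)
})

test_that("degenerate outcomes and constant covariates are explicit errors", {
  d <- sim_glmm_data(n_patients = 100, seed = 7)
  d$y <- 1
  expect_error(fit_random_intercept_logistic(d, "y",
                                             fixed = "institution"),
               "degenerate")
  d2 <- sim_glmm_data(n_patients = 100, seed = 8)
  d2$institution <- factor("site_a", levels = c("site_a", "site_b"))
  expect_error(fit_random_intercept_logistic(d2, "y",
                                             fixed = "institution"),
               "constant")
  d2$y2 <- 1.5
  expect_error(fit_random_intercept_linear(d2, "y2", fixed = "institution"),
               "constant")
  expect_error(fit_random_intercept_logistic(d, "institution",
                                             fixed = "y"), "not binary")
})

test_that("the linear mixed model recovers an institution testing-rate shift", {
  d <- sim_glmm_data(n_patients = 1500, k = 2, beta_inst = 0.8,
                     intercept = 2, re_sd = 0.7, seed = 9,
                     gaussian = TRUE)
  f <- fit_random_intercept_linear(d, "y", fixed = "institution")
  i <- grep("institution", f$coefficients$term)
  expect_equal(f$coefficients$estimate[i], 0.8, tolerance = 0.1)
  expect_equal(f$re_sd, 0.7, tolerance = 0.15)
})

test_that("testing frequency counts tests per inpatient day", {
  b <- tiny_bundle()
  tf <- testing_frequency(b)
  # a1: 2 tests over 3 days; a2: 1 test over 1 day; a3: 2 over 5 days
  expect_equal(tf$rate[match(c("a1", "a2", "a3"), tf$admission_id)],
               c(2 / 3, 1, 2 / 5))
  raw <- testing_frequency(b, denominator = "per_admission")
  expect_equal(raw$rate[match("a1", raw$admission_id)], 2)
  gl <- testing_frequency(b, analyte = "glucose")
  expect_equal(gl$tests[match("a3", gl$admission_id)], 1)
})
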
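test_that("generation is deterministic given the seed", {
  cfg <- oracle_config(n_patients = 120)
  s1 <- generate_cohort(cfg, seed = 99)
  s2 <- generate_cohort(cfg, seed = 99)
  expect_identical(s1$bundle$admissions, s2$bundle$admissions)
  expect_identical(s1$bundle$measurements, s2$bundle$measurements)
  expect_identical(s1$bundle$diagnoses, s2$bundle$diagnoses)
  expect_identical(s1$ledger, s2$ledger)
  s3 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(s1$bundle$measurements, s3$bundle$measurements))
})

test_that("a perfect coder yields diagnosis == lab stratum and kappa = 1", {
  cfg <- oracle_config(n_patients = 400, coding_sens = c(1, 1, 1),
                       coding_fpr = 0, seed = 21)
  sim <- generate_cohort(cfg)
  labs <- label_cohort(sim$bundle, cfg$definitions)
  # with full testing and a perfect coder, diagnosis equals mild-or-worse
  expect_identical(labs$diagnosis_positive, labs$lab_mild)
  for (oc in unique(labs$outcome)) {
    t <- two_by_two(labs, oc, "mild")
    expect_equal(cohen_kappa(t), 1)
  }
})

test_that("an all-none prevalence yields zero positive lab labels", {
  cfg <- oracle_config(n_patients = 150, seed = 31)
  cfg$prevalence <- lapply(cfg$prevalence, function(p) c(1, 0, 0, 0))
  cfg <- labconcord:::validate_simulation_config(unclass(cfg))
  sim <- generate_cohort(cfg)
  labs <- label_cohort(sim$bundle, cfg$definitions)
  expect_identical(sum(labs$lab_mild), 0L)
  expect_identical(sum(labs$lab_severe), 0L)
})

test_that("emitted tables agree with the truth ledger row for row", {
  cfg <- oracle_config(n_patients = 300, seed = 41)
  sim <- generate_cohort(cfg)
  labs <- label_cohort(sim$bundle, cfg$definitions)
  led <- sim$ledger
  key <- paste(labs$admission_id, labs$outcome)
  led <- led[match(key, paste(led$admission_id, led$outcome)), ]
  expect_false(anyNA(led$stratum))
  # severity labels reproduce the latent stratum whenever a lab was drawn
  lab_sev <- ifelse(labs$lab_severe, "severe",
                    ifelse(labs$lab_moderate, "moderate",
                           ifelse(labs$lab_mild, "mild", "none")))
  truth <- ifelse(led$tested, led$stratum, "none")
  expect_identical(lab_sev, truth)
  # every coded diagnosis in the ledger appears in the diagnosis table
  expect_identical(labs$diagnosis_positive, led$coded)
  # each admission belongs to exactly one institution
  inst <- table(sim$bundle$admissions$admission_id)
  expect_true(all(inst == 1))
})

test_that("closed-form concordance matches the hand-evaluated examples", {
  # p = 0.1, sens = 0.2, fpr = 0.02
  cf <- concordance_closed_form(0.1, 0.2, 0.02)
  expect_equal(cf$po, 0.902)
  expect_equal(cf$pe, 0.8696)
  expect_equal(cf$kappa, 0.2485, tolerance = 1e-3)
  # a perfect coder has kappa 1 at any interior prevalence
  for (p in c(0.1, 0.5, 0.9))
    expect_equal(concordance_closed_form(p, 1, 0)$kappa, 1)
  # a coin-flip coder has kappa 0
  expect_equal(concordance_closed_form(0.5, 0.5, 0.5)$kappa, 0)
})

test_that("expected_metrics matches empirical metrics on a large cohort", {
  # study-size simulation, zero intercept SD, full testing: the closed
  # forms are exact and the empirical values are binomial around them
  cfg <- oracle_config(n_patients = 12000, seed = 51)
  sim <- generate_cohort(cfg)
  labs <- label_cohort(sim$bundle, cfg$definitions)
  n <- nrow(sim$bundle$admissions)
  expect_gt(n, 15000)
  m <- concordance_metrics(labs)
  for (oc in c("anemia", "hypoglycemia", "thrombocytopenia")) {
    em <- expected_metrics(cfg, oc)
    for (sev in c("mild", "moderate", "severe")) {
      e <- em[em$severity == sev, ]
      o <- m[m$outcome == oc & m$severity == sev, ]
      npos <- o$tp + o$fn
      se_sens <- sqrt(e$sensitivity * (1 - e$sensitivity) / npos)
      se_spec <- sqrt(e$specificity * (1 - e$specificity) / (n - npos))
      expect_lt(abs(o$sensitivity - e$sensitivity), 3 * se_sens)
      expect_lt(abs(o$specificity - e$specificity), 3 * se_spec)
      # large-sample kappa standard error: sqrt(po(1-po)/n) / (1-pe)
      fpr_eff <- 1 - e$specificity
      cf <- concordance_closed_form(e$prevalence, e$sensitivity, fpr_eff)
      se_kappa <- sqrt(cf$po * (1 - cf$po) / n) / (1 - cf$pe)
      expect_lt(abs(o$kappa - e$kappa), 3 * se_kappa)
    }
  }
})

test_that("the three scenario presets encode their advertised contrasts", {
  ps <- scenario_presets(n_patients = 100)
  expect_setequal(names(ps), c("null", "similar-labs-different-coding",
                               "unit-heterogeneous-coding"))
  null <- ps[["null"]]
  for (fld in c("coding_sens", "coding_fpr", "test_prob_per_day",
                "unit_coding_sd"))
    expect_identical(null[[fld]][["site_a"]], null[[fld]][["site_b"]])
  dif <- ps[["similar-labs-different-coding"]]
  expect_identical(dif$prevalence, null$prevalence)
  expect_true(all(dif$coding_sens$site_b > 2 * dif$coding_sens$site_a))
  het <- ps[["unit-heterogeneous-coding"]]
  expect_gt(het$unit_coding_sd$site_a, het$unit_coding_sd$site_b)
  # invalid configs are rejected with the offending field named
  expect_error(simulation_config(coding_fpr = 1.5), "coding_fpr")
  expect_error(simulation_config(prevalence = list(aki = c(0.5, 0.5))),
               "prevalence.aki")
})
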
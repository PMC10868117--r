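test_that("unit normalization reaches the canonical unit of each analyte", {
  expect_equal(normalize_unit(10, "g/dL", "hemoglobin"), 100)
  # creatinine molar mass 113.12 g/mol: 1 mg/dL = 88.4 umol/L
  expect_equal(normalize_unit(1.0, "mg/dL", "creatinine"), 88.4,
               tolerance = 0.1 / 88.4)
  expect_equal(normalize_unit(4.5, "mEq/L", "potassium"), 4.5)
  expect_equal(normalize_unit(90, "mg/dL", "glucose"), 4.996,
               tolerance = 1e-3)
  expect_equal(normalize_unit(c(1, 2), c("10^9/L", "cells/uL"), "anc"),
               c(1, 0.002))
  expect_error(normalize_unit(1, "furlongs", "sodium"),
               "unrecognized unit 'furlongs' for analyte 'sodium'")
})

test_that("admission extremum follows the outcome direction and handles absence", {
  defs <- default_outcome_definitions()
  m <- data.frame(analyte = "creatinine", value = c(40, 95, 60))
  expect_equal(admission_extremum(m, defs$aki), 95)
  g <- data.frame(analyte = "glucose", value = 5.1)
  expect_equal(admission_extremum(g, defs$hypoglycemia), 5.1)
  expect_true(is.na(admission_extremum(g, defs$hyponatremia)))
})

test_that("severity labels nest and compare strictly against cutoffs", {
  # glucose cutoffs 3.9 / 3.0 / 2.2 mmol/L
  s <- severity_labels(c(1.5, 2.5, 3.5, 3.9, NA), 3.9, 3.0, 2.2, "below")
  expect_equal(s$mild, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(s$moderate, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$severe, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # above direction mirrors (potassium 5.5 / 6.0 / 6.5)
  a <- severity_labels(c(7, 6.2, 5.5), 5.5, 6.0, 6.5, "above")
  expect_equal(a$mild, c(TRUE, TRUE, FALSE))
  expect_equal(a$severe, c(TRUE, FALSE, FALSE))
  # disordered cutoffs are rejected at construction
  expect_error(severity_thresholds(3.0, 3.9, 2.2, "below"), "nest")
})

test_that("abnormal label uses one side of the reference range only", {
  expect_true(abnormal_label(80, 110, 160, "below"))
  expect_false(abnormal_label(4.0, 3.5, 5.5, "above"))
  # a high value under a below-direction outcome is NOT abnormal
  expect_false(abnormal_label(180, 110, 160, "below"))
  expect_false(abnormal_label(NA, 110, 160, "below"))
})

test_that("diagnosis label matches exact or prefix entries, idempotently", {
  aki_codes <- default_outcome_definitions()$aki$code_set
  rec <- function(codes) data.frame(code = codes,
                                    vocabulary = rep("ICD-10", length(codes)),
                                    stringsAsFactors = FALSE)
  expect_true(diagnosis_label(rec("N17.9"), aki_codes))
  expect_false(diagnosis_label(rec(character()), aki_codes))
  expect_identical(diagnosis_label(rec(c("N17.9", "N17.9")), aki_codes),
                   diagnosis_label(rec("N17.9"), aki_codes))
  cs <- code_set("x", data.frame(vocabulary = "ICD-10", code = "E11",
                                 match = "exact"))
  expect_false(diagnosis_label(rec("E11.9"), cs))
  expect_true(diagnosis_label(rec("E11"), cs))
  # vocabulary-restricted entries ignore other vocabularies
  other <- data.frame(code = "N17.9", vocabulary = "local",
                      stringsAsFactors = FALSE)
  expect_false(diagnosis_label(other, aki_codes))
})

test_that("label_cohort reproduces the hand-computed label matrix", {
  labs <- label_cohort(tiny_bundle())
  expect_identical(nrow(labs), 3L * 7L)   # admissions x outcomes

  pick <- function(id, oc) labs[labs$admission_id == id &
                                  labs$outcome == oc, ]
  a1 <- pick("a1", "hypoglycemia")
  expect_true(all(a1$lab_abnormal, a1$lab_mild, a1$lab_moderate,
                  a1$lab_severe, a1$diagnosis_positive))
  expect_equal(a1$extremum_value, 1.5)

  a2 <- pick("a2", "anemia")   # hgb 100: mild only, below infant range
  expect_true(a2$lab_mild && a2$lab_abnormal)
  expect_false(a2$lab_moderate || a2$lab_severe || a2$diagnosis_positive)

  a3 <- pick("a3", "aki")      # code without any creatinine measurement
  expect_true(a3$diagnosis_positive)
  expect_false(any(a3$lab_abnormal, a3$lab_mild))
  expect_true(is.na(a3$extremum_value))

  # everything else is negative
  rest <- labs[!(labs$admission_id == "a1" & labs$outcome == "hypoglycemia") &
                 !(labs$admission_id == "a2" & labs$outcome == "anemia") &
                 !(labs$admission_id == "a3" & labs$outcome == "aki"), ]
  expect_false(any(rest$lab_mild | rest$lab_abnormal |
                     rest$diagnosis_positive))

  # nesting invariant on every row
  expect_true(all(!labs$lab_severe | labs$lab_moderate))
  expect_true(all(!labs$lab_moderate | labs$lab_mild))
})

test_that("labeling is invariant to the reporting units of the input", {
  b <- tiny_bundle()
  alt <- b
  # restate glucose in mg/dL and hemoglobin in g/dL
  gl <- alt$measurements$analyte == "glucose"
  alt$measurements$value[gl] <- alt$measurements$value[gl] * 180.16 / 10
  alt$measurements$unit[gl] <- "mg/dL"
  hb <- alt$measurements$analyte == "hemoglobin"
  alt$measurements$value[hb] <- alt$measurements$value[hb] / 10
  alt$measurements$unit[hb] <- "g/dL"
  l1 <- label_cohort(b)
  l2 <- label_cohort(alt)
  expect_equal(l1$lab_mild, l2$lab_mild)
  expect_equal(l1$lab_abnormal, l2$lab_abnormal)
  expect_equal(l1$extremum_value, l2$extremum_value, tolerance = 1e-12)
})

test_that("labeling is deterministic and monotone in cutoffs", {
  cfg <- oracle_config(n_patients = 150)
  b <- generate_cohort(cfg)$bundle
  l1 <- label_cohort(b, cfg$definitions)
  l2 <- label_cohort(b, cfg$definitions)
  expect_identical(l1, l2)

  # shrinking a below-direction mild cutoff never increases positives
  defs <- cfg$definitions
  base_count <- sum(l1$lab_mild[l1$outcome == "anemia"])
  tighter <- defs
  tighter$anemia$thresholds$mild <- 100   # down from 110
  l3 <- label_cohort(b, tighter)
  expect_lte(sum(l3$lab_mild[l3$outcome == "anemia"]), base_count)

  # a missing reference range is a named error
  rr <- b$reference_ranges
  rr <- rr[!(rr$analyte == "sodium" & rr$age_group == "infant"), ]
  b2 <- b
  b2$reference_ranges <- rr
  expect_error(label_cohort(b2, defs), "sodium")
})
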
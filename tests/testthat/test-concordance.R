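test_that("two_by_two tallies diagnosis against the lab gold standard", {
  labs <- data.frame(
    outcome = "aki",
    lab_abnormal = c(TRUE, TRUE, FALSE, FALSE),
    diagnosis_positive = c(TRUE, FALSE, FALSE, TRUE))
  t <- two_by_two(labs, "aki", "abnormal")
  expect_identical(c(t$tp, t$fn, t$tn, t$fp), c(1L, 1L, 1L, 1L))
  allneg <- data.frame(outcome = "aki", lab_abnormal = FALSE,
                       diagnosis_positive = logical(5))
  t0 <- two_by_two(allneg, "aki")
  expect_identical(c(t0$tp, t0$fp, t0$fn, t0$tn), c(0L, 0L, 0L, 5L))
  expect_error(two_by_two(labs, "anemia"), "no label rows")
})

test_that("cohen_kappa matches hand-worked values and errors when degenerate", {
  expect_equal(cohen_kappa(list(tp = 50, fp = 0, fn = 0, tn = 50)), 1)
  expect_equal(cohen_kappa(list(tp = 25, fp = 25, fn = 25, tn = 25)), 0)
  # po = 0.955, pe = 0.9365 -> kappa = 0.0185 / 0.0635
  expect_equal(cohen_kappa(list(tp = 10, fp = 5, fn = 40, tn = 945)),
               0.0185 / 0.0635, tolerance = 1e-10)
  expect_error(cohen_kappa(list(tp = 0, fp = 0, fn = 0, tn = 10)),
               "degenerate")
})

test_that("kappa is symmetric in the raters and 1 only without discordance", {
  set.seed(1)
  for (i in 1:50) {
    t <- as.list(setNames(rpois(4, 8) + 1, c("tp", "fp", "fn", "tn")))
    swapped <- list(tp = t$tp, fp = t$fn, fn = t$fp, tn = t$tn)
    expect_equal(cohen_kappa(t), cohen_kappa(swapped))
    expect_lt(cohen_kappa(t), 1)   # fp, fn >= 1 here
  }
  expect_equal(cohen_kappa(list(tp = 3, fp = 0, fn = 0, tn = 97)), 1)
})

test_that("sensitivity and specificity are margin ratios, scale-invariant", {
  t <- list(tp = 10, fp = 5, fn = 40, tn = 945)
  expect_equal(sensitivity(t), 0.2)
  expect_equal(specificity(t), 945 / 950)
  t3 <- lapply(t, `*`, 3)
  expect_equal(sensitivity(t3), sensitivity(t))
  expect_equal(specificity(t3), specificity(t))
  expect_error(sensitivity(list(tp = 0, fp = 5, fn = 0, tn = 5)),
               "undefined")
  expect_error(specificity(list(tp = 1, fp = 0, fn = 1, tn = 0)),
               "undefined")
})

test_that("metric summaries report mean/sd and median/range, dropping NAs", {
  m <- data.frame(cohort = "c", severity = "mild",
                  outcome = letters[1:4],
                  kappa = c(0.2, 0.4, 0.6, NA))
  s <- summarize_metrics(m, "kappa")
  expect_equal(s$median, 0.4)
  expect_equal(s$min, 0.2)
  expect_equal(s$max, 0.6)
  expect_equal(s$mean, 0.4)
  expect_equal(s$n, 3L)
  expect_equal(s$n_excluded, 1L)
  one <- summarize_metrics(m[1, ], "kappa")
  expect_equal(one$sd, 0)
  expect_true(one$degenerate)
})

test_that("unit proportions split each admission's weight across its units", {
  labs <- data.frame(
    admission_id = c("a1", "a2", "a3"), outcome = "aki",
    lab_abnormal = c(TRUE, TRUE, FALSE),
    lab_mild = c(TRUE, TRUE, FALSE),
    lab_moderate = c(TRUE, FALSE, FALSE),
    lab_severe = c(TRUE, FALSE, FALSE),
    diagnosis_positive = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  us <- data.frame(admission_id = c("a1", "a1", "a2", "a3"),
                   unit_id = c("A", "B", "A", "B"),
                   stringsAsFactors = FALSE)
  p <- unit_weighted_proportions(labs, us, "aki")
  # unit A: a1 (w=.5, all four severities +) and a2 (w=1, abnormal+mild)
  # lab prop per severity: (.5+1)/1.5, (.5+1)/1.5, .5/1.5, .5/1.5
  A <- p[p$unit_id == "A", ]
  expect_equal(A$lab_prop, mean(c(1, 1, 1 / 3, 1 / 3)))
  expect_equal(A$diag_prop, 0.5 / 1.5)
  # unit B: a1 (w=.5, positive) and a3 (w=1, negative)
  B <- p[p$unit_id == "B", ]
  expect_equal(B$lab_prop, mean(c(1 / 3, 1 / 3, 1 / 3, 1 / 3)))
  # conservation: total weight across units equals admissions
  expect_equal(sum(p$total_weight), 3)

  # single positive admission in a single unit: proportion 1
  p1 <- unit_weighted_proportions(labs[1, ], us[1:2, ], "aki")
  expect_equal(p1$lab_prop, c(1, 1))
  expect_equal(p1$diag_prop, c(1, 1))
})

test_that("spearman_rho uses midranks and matches the classic formula", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  # n=4, d^2 sums to 4: rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  # agreement with stats::cor and invariance under monotone transforms
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15) + x
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_equal(spearman_rho(x, qlogis(plogis(y))), spearman_rho(x, y))
  }
  # midranks: ties handled as average ranks (cross-check vs cor)
  x <- c(1, 1, 2, 3); y <- c(1, 2, 2, 3)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("prevalence table denominates by all cohort admissions", {
  labs <- label_cohort(tiny_bundle())
  prev <- prevalence_table(labs)
  expect_true(all(prev$n_admissions == 3))
  hypo <- prev[prev$outcome == "hypoglycemia" & prev$severity == "severe", ]
  expect_equal(hypo$count, 1L)
  expect_equal(hypo$pct, 33.3)
  # count nesting: severe <= moderate <= mild for every outcome
  for (oc in unique(prev$outcome)) {
    cnt <- setNames(prev$count[prev$outcome == oc],
                    prev$severity[prev$outcome == oc])
    expect_lte(cnt[["severe"]], cnt[["moderate"]])
    expect_lte(cnt[["moderate"]], cnt[["mild"]])
  }
})
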
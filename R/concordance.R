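# Agreement of diagnosis-based labels against lab-based gold standards,
# prevalence tables, metric summaries and per-hospital-unit concordance.

lab_column <- function(severity) {
  stopifnot(severity %in% severity_levels())
  paste0("lab_", severity)
}

#' Two-by-two table of diagnosis label versus lab gold standard
#'
#' Tallies the diagnosis-based label (the "test") against one lab-based
#' label (the gold standard) over all admissions of one outcome.
#'
#' @param labels An `admission_labels` data frame (typically restricted to
#'   one cohort).
#' @param outcome Outcome to tabulate.
#' @param severity Gold-standard severity level: `"abnormal"`, `"mild"`,
#'   `"moderate"` or `"severe"`.
#' @return A `two_by_two` object with counts `tp`, `fp`, `fn`, `tn`
#'   summing to the number of admissions.
#' @export
two_by_two <- function(labels, outcome, severity = "abnormal") {
  rows <- labels[labels$outcome == outcome, , drop = FALSE]
  if (nrow(rows) == 0) abort("no label rows for outcome '%s'", outcome)
  gold <- rows[[lab_column(severity)]]
  test <- rows$diagnosis_positive
  structure(list(tp = sum(test & gold), fp = sum(test & !gold),
                 fn = sum(!test & gold), tn = sum(!test & !gold)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("<two_by_two>  (rows: diagnosis label; cols: lab gold standard)\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("dx+", "dx-"), c("lab+", "lab-")))
  print(m)
  invisible(x)
}

as_two_by_two <- function(t) {
  if (inherits(t, "two_by_two")) return(t)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(t)))
  t <- lapply(t[c("tp", "fp", "fn", "tn")], as.numeric)  # avoid int overflow
  structure(t, class = "two_by_two")
}

#' Cohen's kappa for a two-by-two table
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with observed
#' agreement `po = (tp + tn) / n` and chance agreement
#' `pe = ((tp + fn)(tp + fp) + (fp + tn)(fn + tn)) / n^2`. Undefined (an
#' error) when a margin is degenerate (`pe = 1`), i.e. when either rater
#' is constant.
#'
#' @param t A [two_by_two()] table (or list with `tp`, `fp`, `fn`, `tn`).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(t) {
  t <- lapply(as_two_by_two(t), as.numeric)
  n <- t$tp + t$fp + t$fn + t$tn
  if (n == 0) abort("kappa undefined for an empty table")
  po <- (t$tp + t$tn) / n
  pe <- ((t$tp + t$fn) * (t$tp + t$fp) +
           (t$fp + t$tn) * (t$fn + t$tn)) / n^2
  if (pe >= 1) abort("kappa undefined: a margin is degenerate (pe = 1)")
  (po - pe) / (1 - pe)
}

#' Sensitivity and specificity of the diagnosis label
#'
#' `sensitivity = tp / (tp + fn)`; `specificity = tn / (fp + tn)`, the
#' diagnosis-based label judged against the lab gold standard. A zero
#' denominator is an explicit error, not an `NaN`.
#'
#' @param t A [two_by_two()] table.
#' @return Single numeric in `[0, 1]`.
#' @export
sensitivity <- function(t) {
  t <- as_two_by_two(t)
  if (t$tp + t$fn == 0)
    abort("sensitivity undefined: no gold-standard positives")
  t$tp / (t$tp + t$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(t) {
  t <- as_two_by_two(t)
  if (t$fp + t$tn == 0)
    abort("specificity undefined: no gold-standard negatives")
  t$tn / (t$fp + t$tn)
}

#' Prevalence of positive labels by cohort, severity and outcome
#'
#' Counts and percentages of admissions with each positive label,
#' denominated by all admissions of the cohort (admissions without a
#' qualifying measurement count as negative). Percentages are rendered
#' half-away-from-zero to one decimal.
#'
#' @param labels An `admission_labels` data frame.
#' @param by Column of `labels` defining the cohorts (default
#'   `"institution"`).
#' @return Data frame with columns cohort, severity (the five label
#'   types), outcome, n_admissions, count, pct.
#' @export
prevalence_table <- function(labels, by = "institution") {
  cols <- c(vapply(severity_levels(), lab_column, ""),
            diagnosis = "diagnosis_positive")
  sev_names <- c(severity_levels(), "diagnosis")
  out <- list()
  for (coh in sort(unique(labels[[by]]))) {
    sub <- labels[labels[[by]] == coh, , drop = FALSE]
    n <- length(unique(sub$admission_id))
    for (i in seq_along(cols)) {
      cnt <- tapply(sub[[cols[i]]], sub$outcome, sum)
      out[[length(out) + 1]] <- data.frame(
        cohort = coh, severity = sev_names[i], outcome = names(cnt),
        n_admissions = n, count = as.integer(cnt),
        pct = pct_of(as.integer(cnt), n), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concordance metrics per cohort, severity and outcome
#'
#' Computes kappa, sensitivity and specificity of the diagnosis label
#' against each lab-based gold standard, per cohort and outcome. Metrics
#' that are undefined (degenerate margins or empty denominators) are
#' returned as `NA` rather than erroring, so downstream summaries can
#' drop and count them.
#'
#' @param labels An `admission_labels` data frame.
#' @param by Cohort column (default `"institution"`).
#' @return Data frame with columns cohort, severity, outcome, kappa,
#'   sensitivity, specificity, tp, fp, fn, tn.
#' @export
concordance_metrics <- function(labels, by = "institution") {
  out <- list()
  safe <- function(f, t) tryCatch(f(t), error = function(e) NA_real_)
  for (coh in sort(unique(labels[[by]]))) {
    sub <- labels[labels[[by]] == coh, , drop = FALSE]
    for (sev in severity_levels()) {
      for (oc in sort(unique(sub$outcome))) {
        t <- two_by_two(sub, oc, sev)
        out[[length(out) + 1]] <- data.frame(
          cohort = coh, severity = sev, outcome = oc,
          kappa = safe(cohen_kappa, t),
          sensitivity = safe(sensitivity, t),
          specificity = safe(specificity, t),
          tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary statistics of per-outcome metric values
#'
#' Mean/SD plus median/IQR/range of a metric over outcomes, within each
#' group (typically cohort x severity). Undefined (`NA`) metric values
#' are excluded and counted; a single-value group reports `sd = 0` with
#' `degenerate = TRUE`.
#'
#' @param metrics Output of [concordance_metrics()].
#' @param metric Which metric column to summarize.
#' @param by Grouping columns (default cohort and severity).
#' @return Data frame of group keys plus n, n_excluded, mean, sd, median,
#'   iqr, min, max, degenerate.
#' @export
summarize_metrics <- function(metrics, metric = "kappa",
                              by = c("cohort", "severity")) {
  stopifnot(metric %in% names(metrics))
  key <- interaction(metrics[by], drop = TRUE, sep = "\r")
  out <- lapply(levels(key), function(k) {
    rows <- metrics[key == k, , drop = FALSE]
    v <- rows[[metric]]
    n_excl <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0)
      abort("no defined '%s' values in group %s", metric,
            gsub("\r", " / ", k))
    q <- unname(quantile(v, c(0.25, 0.75)))
    cbind(rows[1, by, drop = FALSE],
          data.frame(metric = metric, n = length(v),
                     n_excluded = n_excl, mean = mean(v),
                     sd = if (length(v) > 1) sd(v) else 0,
                     median = median(v), iqr = q[2] - q[1],
                     min = min(v), max = max(v),
                     degenerate = length(v) == 1))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-hospital-unit weighted label proportions
#'
#' Each admission contributes total weight 1, split equally (1/k) across
#' the k distinct units it visited, so unit proportions conserve the
#' cohort's admission count. The lab proportion is computed per severity
#' level and then averaged across the requested levels; the diagnosis
#' proportion is computed directly.
#'
#' @param labels An `admission_labels` data frame (one cohort).
#' @param unit_stays Unit-stay table (`admission_id`, `unit_id`).
#' @param outcome Outcome to evaluate.
#' @param severities Lab severity levels averaged over (default all four).
#' @return Data frame with columns unit_id, lab_prop, diag_prop,
#'   total_weight.
#' @export
unit_weighted_proportions <- function(labels, unit_stays, outcome,
                                      severities = severity_levels()) {
  rows <- labels[labels$outcome == outcome, , drop = FALSE]
  us <- unit_stays[unit_stays$admission_id %in% rows$admission_id, ,
                   drop = FALSE]
  if (nrow(us) == 0) abort("no unit stays for the labeled admissions")
  k <- table(us$admission_id)
  us$weight <- 1 / as.numeric(k[us$admission_id])
  idx <- match(us$admission_id, rows$admission_id)
  total <- tapply(us$weight, us$unit_id, sum)
  prop_for <- function(flag) {
    pos <- tapply(us$weight * flag[idx], us$unit_id, sum)
    as.numeric(pos / total)
  }
  lab_props <- vapply(severities,
                      function(s) prop_for(rows[[lab_column(s)]]),
                      numeric(length(total)))
  data.frame(unit_id = names(total),
             lab_prop = rowMeans(lab_props),
             diag_prop = prop_for(rows$diagnosis_positive),
             total_weight = as.numeric(total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman rank correlation (midranks for ties)
#'
#' Pearson correlation of average ranks. Errors on constant input, where
#' the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("spearman_rho needs two vectors of equal length >= 3")
  if (var(x) == 0 || var(y) == 0)
    abort("spearman_rho undefined for a constant vector")
  cor(rank(x), rank(y))
}

#' Unit-level lab/diagnosis concordance per cohort and outcome
#'
#' Convenience wrapper: computes [unit_weighted_proportions()] per cohort
#' and outcome and the Spearman correlation between unit lab and
#' diagnosis proportions. With `per_severity = TRUE` the correlation is
#' instead computed per severity level and averaged.
#'
#' @param labels An `admission_labels` data frame.
#' @param unit_stays Unit-stay table.
#' @param by Cohort column.
#' @param per_severity Average per-severity correlations instead of
#'   correlating the severity-averaged lab proportion.
#' @return List with `points` (unit points per cohort x outcome) and
#'   `rho` (data frame cohort, outcome, rho, n_units).
#' @export
unit_concordance <- function(labels, unit_stays, by = "institution",
                             per_severity = FALSE) {
  pts <- list(); rho <- list()
  for (coh in sort(unique(labels[[by]]))) {
    sub <- labels[labels[[by]] == coh, , drop = FALSE]
    for (oc in sort(unique(sub$outcome))) {
      p <- unit_weighted_proportions(sub, unit_stays, oc)
      pts[[length(pts) + 1]] <- cbind(cohort = coh, outcome = oc, p,
                                      stringsAsFactors = FALSE)
      r <- tryCatch({
        if (per_severity) {
          rs <- vapply(severity_levels(), function(s) {
            ps <- unit_weighted_proportions(sub, unit_stays, oc, s)
            tryCatch(spearman_rho(ps$lab_prop, ps$diag_prop),
                     error = function(e) NA_real_)
          }, numeric(1))
          mean(rs, na.rm = TRUE)
        } else spearman_rho(p$lab_prop, p$diag_prop)
      }, error = function(e) NA_real_)
      rho[[length(rho) + 1]] <- data.frame(
        cohort = coh, outcome = oc, rho = r, n_units = nrow(p),
        stringsAsFactors = FALSE)
    }
  }
  list(points = do.call(rbind, pts), rho = do.call(rbind, rho))
}
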
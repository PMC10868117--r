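# Institution effects on labels: random-intercept logistic regression
# (ORs with 99.9% Wald CIs) and random-intercept linear regression for
# testing frequency. Estimation delegates to lme4 (glmer/lmer) with
# adaptive Gauss-Hermite quadrature for the logistic marginal likelihood;
# agq_loglik() provides an independent evaluation of that likelihood for
# cross-checking.

new_glmm_fit <- function(fit, family, nAGQ = NA_integer_,
                         converged = TRUE, singular = FALSE,
                         messages = character()) {
  est <- lme4::fixef(fit)
  se <- suppressWarnings(sqrt(diag(as.matrix(vcov(fit)))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_sd <- vc$sdcor[1]
  structure(list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), stringsAsFactors = FALSE),
    re_sd = re_sd, family = family, nAGQ = nAGQ,
    loglik = as.numeric(logLik(fit)),
    converged = converged, singular = singular,
    n_iter = tryCatch(fit@optinfo$feval %||% NA_integer_,
                      error = function(e) NA_integer_),
    messages = messages, model = fit), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s, random intercept sd = %.4f%s%s\n",
              x$family, x$re_sd,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular]" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

check_fixed_effects <- function(data, fixed) {
  for (f in fixed) {
    if (length(unique(data[[f]])) < 2)
      abort("fixed effect '%s' is constant in the data", f)
  }
}

capture_fit <- function(expr) {
  msgs <- character()
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  list(fit = fit, messages = msgs)
}

#' Random-intercept logistic regression
#'
#' Maximizes the marginal likelihood obtained by integrating a Gaussian
#' per-patient random intercept out of the logistic likelihood, using
#' adaptive Gauss-Hermite quadrature (`lme4::glmer`, `nAGQ` nodes,
#' default 15). Repeat admissions of one patient are thereby modeled as
#' correlated. The reference level of each fixed-effect factor is its
#' first level.
#'
#' @param data Data frame with the outcome, fixed-effect columns and the
#'   grouping column.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param fixed Character vector of fixed-effect column names.
#' @param group Name of the patient-identifier column.
#' @param nAGQ Number of quadrature nodes (>= 1).
#' @param maxit Maximum optimizer evaluations.
#' @return A `glmm_fit` with coefficient estimates (log-odds scale),
#'   standard errors, random-intercept SD, log-likelihood and a
#'   convergence flag.
#' @export
fit_random_intercept_logistic <- function(data, outcome,
                                          fixed = c("institution",
                                                    "age_group"),
                                          group = "patient_id",
                                          nAGQ = 15, maxit = 2e4) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("outcome '%s' is not binary", outcome)
  if (length(unique(y)) < 2)
    abort("outcome '%s' is degenerate (all %d); model is separated",
          outcome, y[1])
  check_fixed_effects(data, fixed)
  d <- data
  d[[".y"]] <- y
  fml <- as.formula(paste(".y ~", paste(fixed, collapse = " + "),
                          "+ (1 |", group, ")"))
  res <- capture_fit(
    lme4::glmer(fml, data = d, family = binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(
                  optCtrl = list(maxfun = maxit),
                  calc.derivs = TRUE)))
  conv <- res$fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", res$messages))
  new_glmm_fit(res$fit, "binomial-logit", nAGQ = nAGQ, converged = conv,
               singular = lme4::isSingular(res$fit),
               messages = res$messages)
}

#' Random-intercept linear regression
#'
#' REML (default) or ML fit of a Gaussian linear mixed model with a
#' per-patient random intercept (`lme4::lmer`), used for outcomes such as
#' lab tests per inpatient day. A singular variance estimate is flagged,
#' not fatal.
#'
#' @param data Data frame.
#' @param outcome Name of the numeric outcome column.
#' @param fixed Fixed-effect column names.
#' @param group Patient-identifier column.
#' @param REML Use REML (default) or ML.
#' @return A `glmm_fit`.
#' @export
fit_random_intercept_linear <- function(data, outcome,
                                        fixed = c("institution",
                                                  "age_group"),
                                        group = "patient_id",
                                        REML = TRUE) {
  y <- data[[outcome]]
  if (!is.numeric(y)) abort("outcome '%s' must be numeric", outcome)
  if (var(y) == 0) abort("outcome '%s' is constant; fit is degenerate",
                         outcome)
  check_fixed_effects(data, fixed)
  d <- data
  d[[".y"]] <- y
  fml <- as.formula(paste(".y ~", paste(fixed, collapse = " + "),
                          "+ (1 |", group, ")"))
  res <- capture_fit(lme4::lmer(fml, data = d, REML = REML))
  new_glmm_fit(res$fit, "gaussian-identity",
               converged = res$fit@optinfo$conv$opt == 0,
               singular = lme4::isSingular(res$fit),
               messages = res$messages)
}

#' Wald confidence interval
#'
#' `estimate +/- z * se` with `z` the standard-normal quantile at
#' `1 - (1 - level) / 2`; at the 99.9% level `z` is about 3.2905. For
#' odds ratios, apply on the log-odds scale and exponentiate.
#'
#' @param estimate Point estimate(s).
#' @param se Standard error(s), positive.
#' @param level Confidence level in (0, 1); default 0.999.
#' @return Matrix with columns `low` and `high`.
#' @export
wald_ci <- function(estimate, se, level = 0.999) {
  stopifnot(all(se >= 0), level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  cbind(low = estimate - z * se, high = estimate + z * se)
}

#' Institution odds ratios for every outcome and label type
#'
#' Fits one random-intercept logistic regression per outcome x label type
#' (abnormal, mild, moderate, severe, diagnosis) — 35 evaluations for the
#' seven default outcomes — with institution and pediatric age group as
#' fixed effects and patient as random intercept. The institution odds
#' ratio is the exponentiated coefficient of the comparator institution
#' versus the reference (first level sorted, or `ref` if given); an OR
#' above 1 means higher odds of a positive label at the comparator. Wald
#' intervals at `level` (default 99.9%). Fit failures are recorded per
#' row (`converged = FALSE`, `NA` estimates), not fatal.
#'
#' @param labels An `admission_labels` data frame for the two pediatric
#'   cohorts.
#' @param ref Reference institution (default: first sorted level).
#' @param level Confidence level (default 0.999).
#' @param nAGQ Quadrature nodes for [fit_random_intercept_logistic()].
#' @param fixed Fixed effects (default institution + age group).
#' @return Data frame with one row per outcome x label type: outcome,
#'   label_type, or, ci_low, ci_high, level, converged, note.
#' @export
or_by_institution <- function(labels, ref = NULL, level = 0.999,
                              nAGQ = 15,
                              fixed = c("institution", "age_group")) {
  insts <- sort(unique(labels$institution))
  if (length(insts) != 2)
    abort("or_by_institution expects exactly 2 institutions, got %d",
          length(insts))
  ref <- ref %||% insts[1]
  comparator <- setdiff(insts, ref)
  label_cols <- c(abnormal = "lab_abnormal", mild = "lab_mild",
                  moderate = "lab_moderate", severe = "lab_severe",
                  diagnosis = "diagnosis_positive")
  out <- list()
  for (oc in sort(unique(labels$outcome))) {
    sub <- labels[labels$outcome == oc, , drop = FALSE]
    sub$institution <- factor(sub$institution, levels = c(ref, comparator))
    sub$age_group <- factor(sub$age_group)
    for (lt in names(label_cols)) {
      row <- tryCatch({
        fit <- fit_random_intercept_logistic(sub, label_cols[[lt]],
                                             fixed = fixed, nAGQ = nAGQ)
        cf <- fit$coefficients
        i <- grep("^institution", cf$term)
        ci <- wald_ci(cf$estimate[i], cf$se[i], level)
        data.frame(outcome = oc, label_type = lt,
                   or = exp(cf$estimate[i]), ci_low = exp(ci[, "low"]),
                   ci_high = exp(ci[, "high"]), level = level,
                   converged = fit$converged, note = "",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(outcome = oc, label_type = lt, or = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, level = level,
                   converged = FALSE, note = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lab testing frequency per admission
#'
#' Tests per inpatient day for each admission: the number of lab
#' measurements divided by `max(1, discharge - admit)` days (the
#' denominator is configurable; `"per_admission"` returns raw counts).
#'
#' @param bundle A `cohort_bundle`.
#' @param analyte Optional single analyte to restrict to.
#' @param denominator `"per_day"` (default) or `"per_admission"`.
#' @return Data frame with admission_id, patient_id, institution,
#'   age_group, tests, days, rate.
#' @export
testing_frequency <- function(bundle, analyte = NULL,
                              denominator = c("per_day",
                                              "per_admission")) {
  denominator <- match.arg(denominator)
  adm <- bundle$admissions
  m <- bundle$measurements
  if (!is.null(analyte)) m <- m[m$analyte == analyte, , drop = FALSE]
  cnt <- table(m$admission_id)
  tests <- as.numeric(cnt[match(adm$admission_id, names(cnt))])
  tests[is.na(tests)] <- 0
  days <- pmax(1, as.numeric(as.Date(adm$discharge_date) -
                               as.Date(adm$admit_date)))
  data.frame(admission_id = adm$admission_id,
             patient_id = adm$patient_id,
             institution = adm$institution,
             age_group = assign_age_group(adm$age_at_admission,
                                          allow_adult = TRUE),
             tests = tests, days = days,
             rate = if (denominator == "per_day") tests / days else tests,
             stringsAsFactors = FALSE)
}

#' Adaptive Gauss-Hermite marginal log-likelihood (independent evaluator)
#'
#' Evaluates the random-intercept logistic marginal log-likelihood
#' directly: for each patient the integrand (Bernoulli likelihood times
#' the Gaussian intercept density) is centered at its mode with a
#' curvature-matched scale, and integrated with an `nodes`-point
#' Gauss-Hermite rule. Written independently of the fitting routine so
#' likelihood values and node-count stability can be cross-checked.
#'
#' @param y Binary response vector.
#' @param X Fixed-effects design matrix (including intercept column).
#' @param group Patient index (factor or integer) aligned with `y`.
#' @param beta Fixed-effect coefficients.
#' @param sigma Random-intercept SD (>= 0).
#' @param nodes Number of quadrature nodes.
#' @return The marginal log-likelihood.
#' @export
agq_loglik <- function(y, X, group, beta, sigma, nodes = 15) {
  stopifnot(length(y) == nrow(X), length(beta) == ncol(X), sigma >= 0)
  g <- as.integer(factor(group))
  G <- max(g)
  log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
  eta0 <- drop(X %*% beta)
  if (sigma == 0) {
    return(sum(y * eta0 - log1pexp(eta0)))
  }
  # per-group Newton iterations for the conditional mode
  b <- rep(0, G)
  for (it in 1:50) {
    mu <- plogis(eta0 + b[g])
    grad <- as.numeric(rowsum(y - mu, g)) - b / sigma^2
    hess <- -(as.numeric(rowsum(mu * (1 - mu), g)) + 1 / sigma^2)
    step <- grad / hess
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- plogis(eta0 + b[g])
  hess <- as.numeric(rowsum(mu * (1 - mu), g)) + 1 / sigma^2
  s <- 1 / sqrt(hess)           # adaptive scale per group
  gh <- pracma::gaussHermite(nodes)
  # log f_g(b) summed within group, evaluated at shifted/scaled nodes
  log_fg <- function(bvec) {
    eta <- eta0 + bvec[g]
    as.numeric(rowsum(y * eta - log1pexp(eta), g)) +
      dnorm(bvec, 0, sigma, log = TRUE)
  }
  acc <- matrix(NA_real_, G, nodes)
  for (k in seq_len(nodes)) {
    bk <- b + sqrt(2) * s * gh$x[k]
    acc[, k] <- log(gh$w[k]) + gh$x[k]^2 + log_fg(bk)
  }
  m <- apply(acc, 1, max)
  sum(m + log(rowSums(exp(acc - m))) + log(sqrt(2) * s))
}
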
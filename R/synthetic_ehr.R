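# Seeded two-institution synthetic EHR generator with known ground truth,
# plus closed-form expected concordance metrics used as oracles.
#
# Generative model, per admission x outcome:
#   latent severity stratum ~ multinomial(P(none), P(mild band),
#     P(moderate band), P(severe band)), with the positive mass optionally
#     shifted on the logit scale by a per-unit case-mix effect;
#   a qualifying lab is drawn with probability 1 - (1 - q)^los (q = per-day
#     testing probability); lab values are uniform within the severity band
#     (the severe band extends one cutoff-width beyond the severe cutoff)
#     and truncated-normal inside the reference range for non-cases;
#   a diagnosis code is emitted with probability
#     plogis(qlogis(sens[stratum]) + patient intercept + unit coding shift)
#     for positive strata and with the false-positive rate otherwise.
# Coding heterogeneity enters on the logit scale, so the association
# module's random-intercept logistic model is correctly specified under
# the generator; per-unit coding shifts are the misspecification toggle.

#' Simulation configuration for the synthetic EHR generator
#'
#' All per-institution arguments are named vectors/lists keyed by
#' institution (scalars are recycled). Probabilities must lie in `[0, 1]`
#' and each outcome's prevalence vector `(none, mild band, moderate band,
#' severe band)` must sum to 1.
#'
#' @param institutions Institution labels.
#' @param n_patients Patients per institution.
#' @param admissions_lambda Mean of the Poisson count added to 1 to give
#'   admissions per patient (so every patient has at least one admission
#'   and repeat admissions induce within-patient correlation).
#' @param los_lambda Mean extra inpatient days (length of stay is
#'   `1 + Poisson(los_lambda)`).
#' @param age_group_probs Named list per institution of length-5
#'   probability vectors over the pediatric age groups.
#' @param test_prob_per_day Per-analyte daily testing probability; a
#'   scalar per institution, or a named vector per analyte.
#' @param mortality_rate In-hospital mortality probability.
#' @param prevalence Named list per outcome: numeric(4) stratum
#'   probabilities `(none, mild, moderate, severe)`.
#' @param coding_sens Named list per institution: numeric(3) coding
#'   sensitivity for the (mild, moderate, severe) strata, applied to all
#'   outcomes, or a named list per outcome of such vectors.
#' @param coding_fpr Coding false-positive rate per institution.
#' @param patient_sd SD of the patient-level random intercept on the
#'   coding logit.
#' @param n_units Hospital units per institution.
#' @param unit_prev_sd SD of the per-unit case-mix shift (logit of the
#'   positive-stratum mass) per institution.
#' @param unit_coding_sd SD of the per-unit coding shift per institution
#'   (0 = homogeneous coding).
#' @param extra_unit_prob Probability an admission visits one additional
#'   unit beyond its primary unit.
#' @param date_window Admission date window (closed).
#' @param reference_ranges Reference-range table used both to draw
#'   non-case values and to label.
#' @param definitions Outcome definitions (thresholds + code sets).
#' @param seed Default RNG seed for [generate_cohort()].
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(institutions = c("site_a", "site_b"),
                              n_patients = 2000,
                              admissions_lambda = 0.65,
                              los_lambda = 1.8,
                              age_group_probs = NULL,
                              test_prob_per_day = 0.25,
                              mortality_rate = 0.005,
                              prevalence = default_prevalence(),
                              coding_sens = c(0.15, 0.30, 0.50),
                              coding_fpr = 0.005,
                              patient_sd = 1,
                              n_units = 10,
                              unit_prev_sd = 0.4,
                              unit_coding_sd = 0,
                              extra_unit_prob = 0.3,
                              date_window = c("2018-06-02", "2022-08-01"),
                              reference_ranges = default_reference_ranges(),
                              definitions = default_outcome_definitions(),
                              seed = 20180602) {
  insts <- institutions
  per_inst <- function(x, what) {
    if (is.list(x) && !is.null(names(x)) && all(insts %in% names(x)))
      return(x[insts])
    if (is.atomic(x) && !is.null(names(x)) && all(insts %in% names(x)))
      return(as.list(x[insts]))
    setNames(rep(list(x), length(insts)), insts)
  }
  default_agp <- setNames(c(0.15, 0.10, 0.17, 0.25, 0.33),
                          age_group_levels())
  cfg <- list(
    institutions = insts,
    n_patients = per_inst(n_patients),
    admissions_lambda = per_inst(admissions_lambda),
    los_lambda = per_inst(los_lambda),
    age_group_probs = per_inst(age_group_probs %||% default_agp),
    test_prob_per_day = per_inst(test_prob_per_day),
    mortality_rate = per_inst(mortality_rate),
    prevalence = prevalence,
    coding_sens = per_inst(coding_sens),
    coding_fpr = per_inst(coding_fpr),
    patient_sd = patient_sd,
    n_units = per_inst(n_units),
    unit_prev_sd = per_inst(unit_prev_sd),
    unit_coding_sd = per_inst(unit_coding_sd),
    extra_unit_prob = per_inst(extra_unit_prob),
    date_window = as.Date(date_window),
    reference_ranges = reference_ranges,
    definitions = definitions,
    seed = seed)
  validate_simulation_config(cfg)
}

default_prevalence <- function() {
  list(aki = c(0.85, 0.08, 0.04, 0.03),
       hyperkalemia = c(0.88, 0.06, 0.035, 0.025),
       hypoglycemia = c(0.88, 0.06, 0.035, 0.025),
       hyponatremia = c(0.80, 0.11, 0.056, 0.034),
       anemia = c(0.50, 0.17, 0.21, 0.12),
       neutropenia = c(0.88, 0.05, 0.035, 0.035),
       thrombocytopenia = c(0.78, 0.11, 0.066, 0.044))
}

validate_simulation_config <- function(cfg) {
  check_prob <- function(x, path) {
    if (any(unlist(x) < 0) || any(unlist(x) > 1))
      abort("config field '%s' has probabilities outside [0, 1]", path)
  }
  for (inst in cfg$institutions) {
    if (cfg$n_patients[[inst]] < 1)
      abort("config field 'n_patients.%s' must be >= 1", inst)
    p <- cfg$age_group_probs[[inst]]
    if (length(p) != 5 || abs(sum(p) - 1) > 1e-8)
      abort("config field 'age_group_probs.%s' must be 5 probabilities summing to 1",
            inst)
    check_prob(cfg$test_prob_per_day[[inst]],
               paste0("test_prob_per_day.", inst))
    check_prob(cfg$mortality_rate[[inst]],
               paste0("mortality_rate.", inst))
    check_prob(cfg$coding_fpr[[inst]], paste0("coding_fpr.", inst))
    cs <- cfg$coding_sens[[inst]]
    if (!is.list(cs)) cs <- list(cs)
    for (v in cs) {
      if (length(v) != 3) abort("coding_sens.%s must have 3 strata", inst)
      check_prob(v, paste0("coding_sens.", inst))
    }
  }
  for (oc in names(cfg$prevalence)) {
    p <- cfg$prevalence[[oc]]
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      abort("config field 'prevalence.%s' must be 4 non-negative probabilities summing to 1",
            oc)
  }
  if (cfg$patient_sd < 0) abort("config field 'patient_sd' must be >= 0")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  for (inst in x$institutions)
    cat(sprintf("  %s: %d patients, %d units, sens=(%s), fpr=%.3g\n",
                inst, x$n_patients[[inst]], x$n_units[[inst]],
                paste(format(coding_sens_for(x, inst, names(x$prevalence)[1])),
                      collapse = ", "),
                x$coding_fpr[[inst]]))
  cat(sprintf("  outcomes: %s\n  patient_sd=%.2f, seed=%d\n",
              paste(names(x$prevalence), collapse = ", "),
              x$patient_sd, x$seed))
  invisible(x)
}

coding_sens_for <- function(cfg, inst, outcome) {
  cs <- cfg$coding_sens[[inst]]
  if (is.list(cs)) cs[[outcome]] else cs
}

test_prob_for <- function(cfg, inst, analyte) {
  q <- cfg$test_prob_per_day[[inst]]
  if (length(q) > 1) unname(q[[analyte]]) else unname(q)
}

# Severity band edges (value space) for a resolved threshold triple.
# Returns a list of [lo, hi) / (lo, hi] matrices per band.
band_edges <- function(mild, moderate, severe, direction) {
  if (direction == "below") {
    w <- moderate - severe
    list(mild = cbind(moderate, mild),
         moderate = cbind(severe, moderate),
         severe = cbind(pmax(0, severe - w), severe))
  } else {
    w <- severe - moderate
    list(mild = cbind(mild, moderate),
         moderate = cbind(moderate, severe),
         severe = cbind(severe, severe + w))
  }
}

# Representative emitted code per outcome (must match the default code
# sets; the generator emits one concrete code per positive coding event).
emit_codes <- function() {
  c(aki = "N17.9", hyperkalemia = "E87.5", hypoglycemia = "E16.2",
    hyponatremia = "E87.1", anemia = "D64.9", neutropenia = "D70.9",
    thrombocytopenia = "D69.6")
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given the seed: the same config and seed reproduce the
#' bundle byte-for-byte. Returns both the emitted tables (a validated
#' `cohort_bundle` in the canonical dialect) and a truth ledger recording,
#' per admission x outcome, the latent severity stratum, whether a
#' qualifying lab was drawn, and the coded-diagnosis indicator with its
#' generating probability.
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return A `synthetic_cohort` list with elements `bundle`, `ledger` and
#'   `unit_effects`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  breaks <- age_group_breaks()
  lower <- breaks[age_group_levels()]
  upper <- c(breaks[age_group_levels()][-1], breaks[["end"]])
  dates <- seq(config$date_window[1], config$date_window[2], by = "day")

  adm_l <- list(); meas_l <- list(); dx_l <- list(); us_l <- list()
  ledger_l <- list(); unit_eff_l <- list()

  for (inst in config$institutions) {
    np <- config$n_patients[[inst]]
    pid <- sprintf("%s_p%05d", inst, seq_len(np))
    n_adm_p <- 1 + rpois(np, config$admissions_lambda[[inst]])
    p_group <- sample(age_group_levels(), np, replace = TRUE,
                      prob = config$age_group_probs[[inst]])
    b_pat <- rnorm(np, 0, config$patient_sd)

    idx <- rep(seq_len(np), n_adm_p)
    n <- length(idx)
    adm_id <- sprintf("%s_a%06d", inst, seq_len(n))
    grp <- p_group[idx]
    gi <- match(grp, age_group_levels())
    age <- floor(runif(n, ceiling(lower[gi]), ceiling(upper[gi])))
    admit <- sample(dates, n, replace = TRUE)
    los <- 1 + rpois(n, config$los_lambda[[inst]])
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(0.47, 0.53))
    died <- runif(n) < config$mortality_rate[[inst]]

    nu <- config$n_units[[inst]]
    unit_ids <- sprintf("%s_u%02d", inst, seq_len(nu))
    u_prev <- rnorm(nu, 0, config$unit_prev_sd[[inst]])
    u_code <- rnorm(nu, 0, config$unit_coding_sd[[inst]])
    primary <- sample.int(nu, n, replace = TRUE)
    extra <- which(runif(n) < config$extra_unit_prob[[inst]] & nu > 1)
    extra_unit <- 1 + (primary[extra] + sample.int(nu - 1, length(extra),
                                                   replace = TRUE) - 1) %% nu
    us_l[[inst]] <- data.frame(
      admission_id = c(adm_id, adm_id[extra]),
      unit_id = unit_ids[c(primary, extra_unit)],
      stringsAsFactors = FALSE)
    unit_eff_l[[inst]] <- data.frame(
      institution = inst, unit_id = unit_ids, prev_shift = u_prev,
      coding_shift = u_code, stringsAsFactors = FALSE)

    adm_l[[inst]] <- data.frame(
      admission_id = adm_id, patient_id = pid[idx], institution = inst,
      admit_date = admit, discharge_date = admit + los,
      age_at_admission = age, sex = sex, died_in_hospital = died,
      stringsAsFactors = FALSE)

    for (oc in names(config$prevalence)) {
      def <- config$definitions[[oc]]
      if (is.null(def)) abort("no outcome definition for '%s'", oc)
      prev <- config$prevalence[[oc]]
      sens <- coding_sens_for(config, inst, oc)
      fpr <- config$coding_fpr[[inst]]
      q <- test_prob_for(config, inst, def$analyte)

      # latent stratum, with per-unit case-mix shift on the logit of the
      # positive mass
      p_pos <- plogis(qlogis(1 - prev[1]) + u_prev[primary])
      band_p <- if (sum(prev[2:4]) > 0) prev[2:4] / sum(prev[2:4])
                else c(1, 0, 0)   # degenerate: no positive mass anyway
      u1 <- runif(n)
      pos <- u1 < p_pos
      stratum <- rep("none", n)
      cum <- cumsum(band_p)
      u2 <- runif(n)
      stratum[pos] <- c("mild", "moderate", "severe")[
        1 + findInterval(u2[pos], cum[1:2])]

      thr <- resolve_thresholds(def, rep(inst, n), grp,
                                config$reference_ranges)
      bands <- band_edges(thr$mild, thr$moderate, thr$severe,
                          def$direction)
      r <- lookup_range(config$reference_ranges, rep(inst, n),
                        rep(def$analyte, n), grp)
      if (def$direction == "below") {
        none_lo <- pmax(r$low, thr$mild); none_hi <- r$high
      } else {
        none_lo <- r$low; none_hi <- pmin(r$high, thr$mild)
      }

      tested <- runif(n) < 1 - (1 - q)^los
      n_tests <- pmax(1L, rbinom(n, los, q)) * tested

      # extremum draw per admission
      val <- rtruncnorm(n, (none_lo + none_hi) / 2,
                        (none_hi - none_lo) / 6, none_lo, none_hi)
      for (bn in c("mild", "moderate", "severe")) {
        sel <- stratum == bn
        if (any(sel))
          val[sel] <- runif(sum(sel), bands[[bn]][sel, 1],
                            bands[[bn]][sel, 2])
      }

      ti <- which(tested)
      reps <- n_tests[ti] - 1L
      ei <- rep(ti, reps)
      extra_vals <- rtruncnorm(length(ei),
                               (none_lo[ei] + none_hi[ei]) / 2,
                               (none_hi[ei] - none_lo[ei]) / 6,
                               none_lo[ei], none_hi[ei])
      all_i <- c(ti, ei)
      all_v <- c(val[ti], extra_vals)
      meas_l[[paste(inst, oc)]] <- data.frame(
        admission_id = adm_id[all_i],
        analyte = def$analyte,
        value = all_v,
        unit = unname(canonical_units()[def$analyte]),
        collected_at = format(admit[all_i] +
                                round(runif(length(all_i)) *
                                        pmax(los[all_i] - 1, 0), 3),
                              "%Y-%m-%dT12:00:00"),
        stringsAsFactors = FALSE)

      p_code <- ifelse(
        stratum == "none", fpr,
        plogis(qlogis(sens[match(stratum,
                                 c("mild", "moderate", "severe"))]) +
                 b_pat[idx] + u_code[primary]))
      coded <- runif(n) < p_code
      ci <- which(coded)
      if (length(ci))
        dx_l[[paste(inst, oc)]] <- data.frame(
          admission_id = adm_id[ci],
          code = unname(emit_codes()[oc]),
          vocabulary = "ICD-10", stringsAsFactors = FALSE)

      ledger_l[[paste(inst, oc)]] <- data.frame(
        admission_id = adm_id, institution = inst, outcome = oc,
        stratum = stratum, tested = tested, coded = coded,
        coding_prob = p_code, stringsAsFactors = FALSE)
    }
  }

  bundle <- cohort_bundle(
    admissions = do.call(rbind, unname(adm_l)),
    measurements = do.call(rbind, unname(meas_l)),
    diagnoses = do.call(rbind, unname(dx_l)),
    unit_stays = do.call(rbind, unname(us_l)),
    reference_ranges = config$reference_ranges)
  ledger <- do.call(rbind, unname(ledger_l))
  rownames(ledger) <- NULL
  structure(list(bundle = bundle, ledger = ledger,
                 unit_effects = do.call(rbind, unname(unit_eff_l)),
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> seed %d\n", x$seed))
  print(x$bundle)
  invisible(x)
}

#' Closed-form concordance of a binary coder against a gold standard
#'
#' Given gold-standard prevalence `p`, coder sensitivity `sens` and
#' false-positive rate `fpr`, the observed agreement is
#' `po = p * sens + (1 - p)(1 - fpr)`, the coder's positive rate is
#' `q = p * sens + (1 - p) * fpr`, chance agreement is
#' `pe = q * p + (1 - q)(1 - p)`, and `kappa = (po - pe) / (1 - pe)`.
#'
#' @param p Gold-standard prevalence.
#' @param sens Coder sensitivity.
#' @param fpr Coder false-positive rate.
#' @return List with prevalence, sensitivity, specificity, po, pe, kappa.
#' @export
concordance_closed_form <- function(p, sens, fpr) {
  po <- p * sens + (1 - p) * (1 - fpr)
  q <- p * sens + (1 - p) * fpr
  pe <- q * p + (1 - q) * (1 - p)
  list(prevalence = p, sensitivity = sens, specificity = 1 - fpr,
       po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

# marginal coding probability over the patient intercept (Gauss-Hermite)
marginal_prob <- function(a, sd, nodes = 40) {
  if (sd == 0 || a %in% c(0, 1)) return(a)
  gh <- pracma::gaussHermite(nodes)
  sum(gh$w / sqrt(pi) * plogis(qlogis(a) + sqrt(2) * sd * gh$x))
}

#' Expected concordance metrics under a simulation configuration
#'
#' Analytic expectation of prevalence, sensitivity, specificity and kappa
#' of the diagnosis label against each nested lab severity level (mild,
#' moderate, severe), for one outcome and institution. Exact when the
#' patient intercept SD is 0; otherwise stratum sensitivities are
#' marginalized over the intercept by Gauss-Hermite quadrature.
#' Assumes no per-unit effects (a warning is issued if the config has
#' any); the `abnormal` label is not covered because its expectation
#' depends on where reference-range bounds sit relative to the severity
#' cutoffs.
#'
#' Accounts for incomplete testing: a positive-stratum admission without
#' a qualifying lab is a gold-standard negative that is still coded with
#' the stratum sensitivity, which depresses specificity — exactly as in
#' real coding-versus-lab comparisons.
#'
#' @param config A [simulation_config()].
#' @param outcome Outcome name.
#' @param institution Institution name (default first).
#' @return Data frame with one row per severity level: severity,
#'   prevalence, sensitivity, specificity, kappa.
#' @export
expected_metrics <- function(config, outcome,
                             institution = config$institutions[1]) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$unit_prev_sd[[institution]] != 0 ||
      config$unit_coding_sd[[institution]] != 0)
    warning("expected_metrics ignores per-unit effects; config has nonzero unit SDs")
  prev <- config$prevalence[[outcome]]
  def <- config$definitions[[outcome]]
  a <- vapply(coding_sens_for(config, institution, outcome),
              marginal_prob, numeric(1), sd = config$patient_sd)
  f <- config$coding_fpr[[institution]]
  q <- test_prob_for(config, institution, def$analyte)
  lam <- config$los_lambda[[institution]]
  k <- 0:300
  p_test <- sum(dpois(k, lam) * (1 - (1 - q)^(1 + k)))

  pi_band <- prev[2:4]          # mild, moderate, severe band masses
  rows <- lapply(1:3, function(s) {
    pos_mass <- sum(pi_band[s:3])
    p <- p_test * pos_mass
    sens <- sum(pi_band[s:3] * a[s:3]) / pos_mass
    below <- if (s > 1) sum(pi_band[1:(s - 1)] * a[1:(s - 1)]) else 0
    fpr_eff <- (prev[1] * f + below + (1 - p_test) * sum(pi_band[s:3] * a[s:3])) /
      (1 - p)
    cf <- concordance_closed_form(p, sens, fpr_eff)
    data.frame(severity = c("mild", "moderate", "severe")[s],
               prevalence = p, sensitivity = sens,
               specificity = cf$specificity, kappa = cf$kappa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Named scenario presets for the synthetic generator
#'
#' Three study scenarios (cohort sizes default to roughly one tenth of a
#' large two-institution pediatric study; pass `n_patients` to rescale):
#' \describe{
#'   \item{null}{Both institutions identical in every parameter; all
#'     institution odds ratios are 1 in expectation.}
#'   \item{similar-labs-different-coding}{Identical lab prevalence and
#'     similar testing, but coding sensitivity an order of magnitude
#'     higher at `site_b`; diagnosis-label ORs far exceed lab-label ORs.}
#'   \item{unit-heterogeneous-coding}{Same coding sensitivity on average,
#'     but `site_a` adds a large per-unit coding shift, which lowers the
#'     unit-level lab-versus-diagnosis Spearman correlation there.}
#' }
#'
#' @param n_patients Patients per institution, a scalar or named vector
#'   (default `c(site_a = 3600, site_b = 1500)`).
#' @param seed Seed stored in each config.
#' @return Named list of [simulation_config()]s.
#' @export
scenario_presets <- function(n_patients = c(site_a = 3600, site_b = 1500),
                             seed = 20180602) {
  agp <- list(
    site_a = setNames(c(0.151, 0.095, 0.173, 0.250, 0.331),
                      age_group_levels()),
    site_b = setNames(c(0.157, 0.092, 0.175, 0.246, 0.330),
                      age_group_levels()))
  base <- function(...) {
    simulation_config(
      institutions = c("site_a", "site_b"),
      n_patients = n_patients,
      admissions_lambda = c(site_a = 0.62, site_b = 0.70),
      los_lambda = c(site_a = 1.6, site_b = 2.0),
      age_group_probs = agp,
      mortality_rate = c(site_a = 0.005, site_b = 0.008),
      patient_sd = 1,
      seed = seed,
      ...)
  }
  list(
    "null" = base(
      test_prob_per_day = 0.25,
      coding_sens = c(0.15, 0.30, 0.50),
      coding_fpr = 0.005,
      n_units = 12, unit_prev_sd = 0.4, unit_coding_sd = 0),
    "similar-labs-different-coding" = base(
      test_prob_per_day = c(site_a = 0.22, site_b = 0.30),
      coding_sens = list(site_a = c(0.04, 0.08, 0.15),
                         site_b = c(0.30, 0.50, 0.70)),
      coding_fpr = c(site_a = 0.002, site_b = 0.012),
      n_units = 12, unit_prev_sd = 0.4, unit_coding_sd = 0),
    "unit-heterogeneous-coding" = base(
      test_prob_per_day = 0.25,
      coding_sens = c(0.20, 0.35, 0.55),
      coding_fpr = 0.005,
      n_units = 15, unit_prev_sd = 0.8,
      unit_coding_sd = c(site_a = 1.5, site_b = 0)))
}
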
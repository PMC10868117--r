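# Outcome definitions: analyte units, severity thresholds, reference
# ranges and diagnosis code sets. All rule tables are configuration, not
# code: the shipped defaults are editable stand-ins.

#' Canonical unit per analyte
#'
#' Creatinine umol/L; potassium, sodium and glucose mmol/L; absolute
#' neutrophil count and platelets 10^9/L; hemoglobin g/L.
#'
#' @return Named character vector keyed by analyte.
#' @export
canonical_units <- function() {
  c(creatinine = "umol/L", potassium = "mmol/L", glucose = "mmol/L",
    sodium = "mmol/L", anc = "10^9/L", hemoglobin = "g/L",
    platelets = "10^9/L")
}

# Multiplicative factors from a recognized reporting unit to the canonical
# unit. Creatinine mg/dL -> umol/L uses molar mass 113.12 g/mol
# (10000 / 113.12); glucose mg/dL -> mmol/L uses 180.16 g/mol.
unit_conversion_table <- function() {
  list(
    creatinine = c("umol/L" = 1, "\u00b5mol/L" = 1, "mmol/L" = 1000,
                   "mg/dL" = 10000 / 113.12),
    potassium = c("mmol/L" = 1, "mEq/L" = 1),
    sodium = c("mmol/L" = 1, "mEq/L" = 1),
    glucose = c("mmol/L" = 1, "mg/dL" = 10 / 180.16,
                "g/L" = 1000 / 180.16),
    anc = c("10^9/L" = 1, "x10^9/L" = 1, "10*9/L" = 1, "10e9/L" = 1,
            "cells/uL" = 1e-3, "/uL" = 1e-3),
    hemoglobin = c("g/L" = 1, "g/dL" = 10),
    platelets = c("10^9/L" = 1, "x10^9/L" = 1, "10*9/L" = 1,
                  "10e9/L" = 1, "x10^3/uL" = 1, "1000/uL" = 1)
  )
}

#' Normalize a lab value to the canonical unit of its analyte
#'
#' @param value Numeric value(s).
#' @param unit Reporting unit string(s), recycled against `value`.
#' @param analyte Single analyte name (see [canonical_units()]).
#' @return Value(s) in the canonical unit.
#' @export
normalize_unit <- function(value, unit, analyte) {
  conv <- unit_conversion_table()[[analyte]]
  if (is.null(conv)) abort("unknown analyte '%s'", analyte)
  f <- conv[unit]
  if (anyNA(f))
    abort("unrecognized unit '%s' for analyte '%s'",
          unit[which(is.na(f))[1]], analyte)
  unname(value * f)
}

#' Severity threshold triple for one outcome
#'
#' Cutoffs must be ordered so severity nests: for `direction = "below"`
#' `mild >= moderate >= severe`; for `"above"` `mild <= moderate <=
#' severe`. With `mode = "relative_to_reference_high"` the cutoffs are
#' multipliers of the admission's age-group upper reference bound (used
#' for hypercreatinemia-based AKI); with `"absolute"` they are values in
#' `unit`.
#'
#' @param mild,moderate,severe Numeric cutoffs (or multipliers).
#' @param direction `"above"` or `"below"`.
#' @param mode `"absolute"` or `"relative_to_reference_high"`.
#' @param unit Canonical unit the cutoffs are expressed in.
#' @return A `severity_thresholds` object.
#' @export
severity_thresholds <- function(mild, moderate, severe,
                                direction = c("below", "above"),
                                mode = c("absolute",
                                         "relative_to_reference_high"),
                                unit = NA_character_) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  ok <- if (direction == "below") mild >= moderate && moderate >= severe
        else mild <= moderate && moderate <= severe
  if (!ok)
    abort("cutoffs (%s, %s, %s) do not nest for direction '%s'",
          mild, moderate, severe, direction)
  structure(list(mild = mild, moderate = moderate, severe = severe,
                 direction = direction, mode = mode, unit = unit),
            class = "severity_thresholds")
}

#' Diagnosis code set for one outcome
#'
#' @param outcome Outcome name.
#' @param entries Data frame with columns `vocabulary`, `code`, `match`
#'   (`"exact"` or `"prefix"`). An empty/`NA` vocabulary matches records
#'   from any vocabulary.
#' @return A `code_set` object.
#' @export
code_set <- function(outcome, entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("vocabulary", "code", "match") %in% names(entries)))
  if (nrow(entries) == 0) abort("code set for '%s' is empty", outcome)
  if (!all(entries$match %in% c("exact", "prefix")))
    abort("code set match mode must be 'exact' or 'prefix'")
  structure(list(outcome = outcome, entries = entries),
            class = "code_set")
}

#' Full definition of one lab-based outcome
#'
#' Binds the analyte, the abnormal direction (one side of the reference
#' range only), the per-admission extremum that side implies (maximum for
#' `"above"`, minimum for `"below"`), the severity thresholds and the
#' diagnosis code set.
#'
#' @param outcome Outcome name.
#' @param analyte Analyte name.
#' @param direction `"above"` or `"below"`.
#' @param thresholds A [severity_thresholds()].
#' @param codes A [code_set()].
#' @return An `outcome_definition` object.
#' @export
outcome_definition <- function(outcome, analyte, direction, thresholds,
                               codes) {
  stopifnot(inherits(thresholds, "severity_thresholds"),
            inherits(codes, "code_set"))
  if (thresholds$direction != direction)
    abort("thresholds direction '%s' disagrees with outcome direction '%s'",
          thresholds$direction, direction)
  structure(list(outcome = outcome, analyte = analyte,
                 direction = direction,
                 extremum = if (direction == "above") "max" else "min",
                 thresholds = thresholds, code_set = codes),
            class = "outcome_definition")
}

#' Load the default (or a custom) set of outcome definitions
#'
#' Parses the severity-threshold and code-set configuration files into a
#' named list of [outcome_definition()]s. The shipped defaults cover the
#' seven outcomes of [lab_outcomes()].
#'
#' @param thresholds_file YAML file of severity thresholds.
#' @param code_sets_file YAML file of diagnosis code sets.
#' @return Named list of `outcome_definition` objects.
#' @export
default_outcome_definitions <- function(
    thresholds_file = system.file("extdata", "severity_thresholds.yaml",
                                  package = "labconcord"),
    code_sets_file = system.file("extdata", "code_sets.yaml",
                                 package = "labconcord")) {
  thr <- yaml::read_yaml(thresholds_file)
  cs <- yaml::read_yaml(code_sets_file)
  defs <- lapply(names(thr), function(oc) {
    t <- thr[[oc]]
    entries <- cs[[oc]]
    if (is.null(entries))
      abort("no code set configured for outcome '%s'", oc)
    entries <- do.call(rbind, lapply(entries, function(e)
      data.frame(vocabulary = e$vocabulary %||% NA_character_,
                 code = e$code, match = e$match %||% "exact",
                 stringsAsFactors = FALSE)))
    outcome_definition(
      outcome = oc, analyte = t$analyte, direction = t$direction,
      thresholds = severity_thresholds(
        t$mild, t$moderate, t$severe, direction = t$direction,
        mode = t$threshold_mode %||% "absolute",
        unit = t$unit %||% canonical_units()[[t$analyte]]),
      codes = code_set(oc, entries))
  })
  setNames(defs, names(thr))
}

#' Default institution/age-group reference ranges (synthetic)
#'
#' A synthetic two-institution reference-range table in canonical units,
#' constructed to be clinically plausible for pediatric age groups and to
#' differ between the two institutions (as real institutional ranges do).
#' Replace with local laboratory ranges for real analyses.
#'
#' @param file CSV file with columns institution, analyte, age_group,
#'   low, high, unit.
#' @return Data frame of reference ranges.
#' @export
default_reference_ranges <- function(
    file = system.file("extdata", "reference_ranges_synthetic.csv",
                       package = "labconcord")) {
  read.csv(file, stringsAsFactors = FALSE)
}

# Look up the (low, high) range rows for given keys; vectorized over the
# admission-level key triple. Errors naming the first missing triple.
lookup_range <- function(ranges, institution, analyte, age_group) {
  key <- paste(institution, analyte, age_group, sep = "\r")
  tab_key <- paste(ranges$institution, ranges$analyte, ranges$age_group,
                   sep = "\r")
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    abort("no reference range for institution '%s', analyte '%s', age group '%s'",
          institution[i], analyte[i], age_group[i])
  }
  list(low = ranges$low[idx], high = ranges$high[idx])
}

#' Resolve severity cutoffs for a given admission context
#'
#' Absolute thresholds are returned unchanged; relative thresholds are
#' multiplied by the upper reference bound for the admission's
#' institution/analyte/age group.
#'
#' @param definition An [outcome_definition()].
#' @param institution,age_group Vectors of admission context (recycled).
#' @param ranges Reference-range table.
#' @return List of numeric vectors `mild`, `moderate`, `severe`.
#' @export
resolve_thresholds <- function(definition, institution, age_group,
                               ranges = default_reference_ranges()) {
  thr <- definition$thresholds
  n <- max(length(institution), length(age_group))
  if (thr$mode == "absolute")
    return(list(mild = rep(thr$mild, n), moderate = rep(thr$moderate, n),
                severe = rep(thr$severe, n)))
  r <- lookup_range(ranges, rep_len(institution, n),
                    rep_len(definition$analyte, n),
                    rep_len(age_group, n))
  list(mild = thr$mild * r$high, moderate = thr$moderate * r$high,
       severe = thr$severe * r$high)
}
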
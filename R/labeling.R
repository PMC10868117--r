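# Per-admission outcome labels: four lab-based labels (abnormal via
# reference range; nested mild/moderate/severe via thresholds) and one
# diagnosis-code label.

#' Per-admission extremum of an analyte
#'
#' The maximum (for above-direction outcomes) or minimum (below) of the
#' admission's normalized values for the definition's analyte; `NA` when
#' the admission has no measurement of that analyte.
#'
#' @param measurements Measurement rows for one admission, with values
#'   already in the canonical unit.
#' @param definition An [outcome_definition()].
#' @return A single numeric value, or `NA` when no measurement exists.
#' @export
admission_extremum <- function(measurements, definition) {
  v <- measurements$value[measurements$analyte == definition$analyte]
  if (length(v) == 0) return(NA_real_)
  if (definition$extremum == "max") max(v) else min(v)
}

#' Nested severity labels from an extremum
#'
#' Strict comparison against each cutoff: for `direction = "below"`,
#' mild is `extremum < mild cutoff` and likewise for moderate and severe
#' (mirrored with `>` for `"above"`). The cutoff ordering guarantees
#' nesting (severe implies moderate implies mild). A missing extremum
#' (no measurement) yields all-`FALSE`.
#'
#' @param extremum Numeric vector of per-admission extrema (may contain
#'   `NA`).
#' @param mild,moderate,severe Cutoff vectors (recycled).
#' @param direction `"above"` or `"below"`.
#' @return Data frame with logical columns `mild`, `moderate`, `severe`.
#' @export
severity_labels <- function(extremum, mild, moderate, severe,
                            direction = c("below", "above")) {
  direction <- match.arg(direction)
  cmp <- if (direction == "below") `<` else `>`
  lab <- function(cut) {
    x <- cmp(extremum, cut)
    x[is.na(x)] <- FALSE
    x
  }
  data.frame(mild = lab(mild), moderate = lab(moderate),
             severe = lab(severe))
}

#' Abnormal label from the institution reference range
#'
#' One-sided by design: only the declared direction of the range is
#' consulted (below -> `extremum < low`; above -> `extremum > high`), so
#' an out-of-range value on the opposite side does not count. Missing
#' extremum yields `FALSE`.
#'
#' @param extremum Numeric vector (may contain `NA`).
#' @param low,high Reference-range bounds (recycled).
#' @param direction `"above"` or `"below"`.
#' @return Logical vector.
#' @export
abnormal_label <- function(extremum, low, high,
                           direction = c("below", "above")) {
  direction <- match.arg(direction)
  x <- if (direction == "below") extremum < low else extremum > high
  x[is.na(x)] <- FALSE
  x
}

# Which admission_ids have >= 1 record matching the code set
matched_admissions <- function(diagnoses, codes) {
  if (nrow(diagnoses) == 0) return(character())
  hit <- rep(FALSE, nrow(diagnoses))
  for (i in seq_len(nrow(codes$entries))) {
    e <- codes$entries[i, ]
    m <- if (e$match == "prefix") startsWith(diagnoses$code, e$code)
         else diagnoses$code == e$code
    if (!is.na(e$vocabulary) && nzchar(e$vocabulary))
      m <- m & diagnoses$vocabulary == e$vocabulary
    hit <- hit | m
  }
  unique(diagnoses$admission_id[hit])
}

#' Diagnosis-based label for one admission
#'
#' `TRUE` iff at least one diagnosis record matches an entry of the code
#' set (exact or prefix match per entry). Duplicated codes count once.
#'
#' @param records Diagnosis rows for one admission (columns `code`,
#'   `vocabulary`); an empty data frame yields `FALSE`.
#' @param codes A [code_set()].
#' @return Single logical.
#' @export
diagnosis_label <- function(records, codes) {
  if (is.null(records) || nrow(records) == 0) return(FALSE)
  records$admission_id <- "x"
  length(matched_admissions(records, codes)) > 0
}

# grouped extremum over the measurement table; returns vector aligned
# with `ids`
extrema_by_admission <- function(measurements, analyte, extremum, ids) {
  m <- measurements[measurements$analyte == analyte, , drop = FALSE]
  if (nrow(m) == 0) return(rep(NA_real_, length(ids)))
  fun <- if (extremum == "max") max else min
  ext <- tapply(m$value, m$admission_id, fun)
  unname(ext[match(ids, names(ext))])
}

#' Label every admission of a cohort for every outcome
#'
#' Normalizes measurement units, takes the per-admission extremum of each
#' outcome's analyte, and derives the five labels. Admissions with no
#' measurement of an analyte are labeled negative, not excluded, so
#' prevalence denominators are all admissions (a measurement-ascertainment
#' caveat worth keeping in mind when interpreting results). The output
#' always satisfies the nesting invariant `severe => moderate => mild`;
#' `abnormal` is an independent reference-range label and does not nest
#' with the severity triple.
#'
#' @param bundle A `cohort_bundle`.
#' @param definitions Named list of [outcome_definition()]s.
#' @param reference_ranges Optional override of the bundle's range table.
#' @return Data frame of class `admission_labels` with one row per
#'   admission x outcome: `admission_id`, `patient_id`, `institution`,
#'   `age_group`, `outcome`, `lab_abnormal`, `lab_mild`, `lab_moderate`,
#'   `lab_severe`, `diagnosis_positive`, `extremum_value`.
#' @export
label_cohort <- function(bundle, definitions = default_outcome_definitions(),
                         reference_ranges = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  adm <- bundle$admissions
  ranges <- reference_ranges %||% bundle$reference_ranges
  age_group <- assign_age_group(adm$age_at_admission, allow_adult = TRUE)

  meas <- bundle$measurements
  if (nrow(meas)) {
    # normalize once, grouped by (analyte, unit)
    for (a in unique(meas$analyte)) {
      sel <- meas$analyte == a
      meas$value[sel] <- normalize_unit(meas$value[sel], meas$unit[sel], a)
    }
    meas$unit <- canonical_units()[meas$analyte]
  }

  out <- lapply(definitions, function(def) {
    ext <- extrema_by_admission(meas, def$analyte, def$extremum,
                                adm$admission_id)
    thr <- resolve_thresholds(def, adm$institution, age_group, ranges)
    sev <- severity_labels(ext, thr$mild, thr$moderate, thr$severe,
                           def$direction)
    r <- lookup_range(ranges, adm$institution,
                      rep_len(def$analyte, nrow(adm)), age_group)
    abn <- abnormal_label(ext, r$low, r$high, def$direction)
    pos_ids <- matched_admissions(bundle$diagnoses, def$code_set)
    data.frame(admission_id = adm$admission_id,
               patient_id = adm$patient_id,
               institution = adm$institution,
               age_group = age_group,
               outcome = def$outcome,
               lab_abnormal = abn,
               lab_mild = sev$mild,
               lab_moderate = sev$moderate,
               lab_severe = sev$severe,
               diagnosis_positive = adm$admission_id %in% pos_ids,
               extremum_value = ext,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  stopifnot(all(!res$lab_severe | res$lab_moderate),
            all(!res$lab_moderate | res$lab_mild))
  class(res) <- c("admission_labels", "data.frame")
  res
}
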
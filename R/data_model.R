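# Canonical in-memory tables, file readers for two column dialects,
# cohort eligibility and pediatric age groups.

#' Pediatric age-group boundaries in days
#'
#' NICHD-style pediatric groups at day resolution: infant `[28 d, 366 d)`,
#' toddler `[366 d, 3 y)`, early childhood `[3 y, 6 y)`, middle childhood
#' `[6 y, 12 y)`, early adolescence `[12 y, 18 y)`. A year is
#' `days_per_year` days; the month/year group labels used in clinical
#' reporting are ambiguous at their edges, so each group is taken to start
#' where the previous named range is exceeded, and the conversion is
#' exposed here rather than hard-coded.
#'
#' @param days_per_year Days per year used to convert year boundaries
#'   (default 365.25).
#' @return Named numeric vector of lower boundaries plus the exclusive
#'   upper end (`end`), in days.
#' @export
age_group_breaks <- function(days_per_year = 365.25) {
  c(infant = 28,
    toddler = 366,
    early_childhood = 3 * days_per_year,
    middle_childhood = 6 * days_per_year,
    early_adolescence = 12 * days_per_year,
    end = 18 * days_per_year)
}

age_group_levels <- function() {
  c("infant", "toddler", "early_childhood", "middle_childhood",
    "early_adolescence")
}

#' Assign the pediatric age group for an age in days
#'
#' @param age_days Integer age(s) at admission, in days.
#' @param breaks Boundaries as returned by [age_group_breaks()].
#' @param allow_adult If `TRUE`, ages at or beyond the pediatric range map
#'   to `"adult"` instead of erroring.
#' @return Character vector of age groups (one of
#'   infant/toddler/early_childhood/middle_childhood/early_adolescence,
#'   plus `"adult"` when allowed).
#' @export
assign_age_group <- function(age_days, breaks = age_group_breaks(),
                             allow_adult = FALSE) {
  stopifnot(is.numeric(age_days))
  lower <- breaks[age_group_levels()]
  upper <- breaks[["end"]]
  out <- rep(NA_character_, length(age_days))
  adult <- age_days >= upper
  if (any(adult)) {
    if (!allow_adult)
      abort("age %s days is outside the pediatric range [28, %s)",
            age_days[adult][1], upper)
    out[adult] <- "adult"
  }
  ped <- !adult
  if (any(age_days[ped] < lower[1], na.rm = TRUE))
    abort("age %s days is below the pediatric minimum of 28 days",
          min(age_days[ped], na.rm = TRUE))
  idx <- findInterval(age_days[ped], lower)
  out[ped] <- age_group_levels()[idx]
  out
}

#' Cohort eligibility configuration
#'
#' @param date_window Length-2 vector (coercible to `Date`) of the first
#'   and last eligible admission date; the window is closed on both ends.
#' @param age_rule `"pediatric"` keeps `28 days <= age < 18 years`;
#'   `"adult"` keeps `age >= 18 years`.
#' @param institution Optional institution label to restrict to.
#' @param days_per_year Days per year used for the 18-year boundary.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(date_window = c("2018-06-02", "2022-08-01"),
                          age_rule = c("pediatric", "adult"),
                          institution = NULL,
                          days_per_year = 365.25) {
  age_rule <- match.arg(age_rule)
  window <- as.Date(date_window)
  if (length(window) != 2L || any(is.na(window)) || window[1] > window[2])
    abort("date_window must be two valid dates with start <= end")
  structure(list(date_window = window, age_rule = age_rule,
                 institution = institution,
                 days_per_year = days_per_year),
            class = "cohort_config")
}

#' Apply cohort eligibility to an admissions table
#'
#' Keeps admissions whose admit date falls inside the closed date window
#' and whose age at admission satisfies the age rule (pediatric:
#' `28 days <= age < 18 years`, excluding neonates aged 1–27 days; adult:
#' `age >= 18 years`). Multiple admissions per patient are retained.
#' Idempotent: filtering an already-filtered table changes nothing.
#'
#' @param admissions Admissions data frame (see [read_bundle()]).
#' @param config A [cohort_config()].
#' @return The eligible subset of `admissions`.
#' @export
filter_eligible <- function(admissions, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  adm <- admissions
  d <- as.Date(adm$admit_date)
  keep <- d >= config$date_window[1] & d <= config$date_window[2]
  adult_min <- 18 * config$days_per_year
  keep <- keep & if (config$age_rule == "pediatric") {
    adm$age_at_admission >= 28 & adm$age_at_admission < adult_min
  } else {
    adm$age_at_admission >= adult_min
  }
  if (!is.null(config$institution))
    keep <- keep & adm$institution == config$institution
  adm[which(keep), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Bundle construction and validation

bundle_tables <- function() {
  c("admissions", "measurements", "diagnoses", "unit_stays",
    "reference_ranges")
}

required_columns <- function() {
  list(
    admissions = c("admission_id", "patient_id", "institution",
                   "admit_date", "discharge_date", "age_at_admission",
                   "sex", "died_in_hospital"),
    measurements = c("admission_id", "analyte", "value", "unit",
                     "collected_at"),
    diagnoses = c("admission_id", "code", "vocabulary"),
    unit_stays = c("admission_id", "unit_id"),
    reference_ranges = c("institution", "analyte", "age_group", "low",
                         "high", "unit")
  )
}

#' Column maps for the supported file dialects
#'
#' Two delimited-text dialects are read behind one interface: `"flat"`
#' (canonical column names) and `"omop"` (OMOP-CDM-style
#' measurement / condition_occurrence / visit column naming). A map is a
#' named list of named character vectors, `canonical = file_column`,
#' one per table; pass a modified copy to [read_bundle()] to support a
#' local schema.
#'
#' @param dialect `"flat"` or `"omop"`.
#' @return Named list of per-table column maps.
#' @export
dialect_column_map <- function(dialect = c("flat", "omop")) {
  dialect <- match.arg(dialect)
  req <- required_columns()
  if (dialect == "flat")
    return(lapply(req, function(cols) setNames(cols, cols)))
  list(
    admissions = c(admission_id = "visit_occurrence_id",
                   patient_id = "person_id",
                   institution = "care_site_source_value",
                   admit_date = "visit_start_date",
                   discharge_date = "visit_end_date",
                   age_at_admission = "age_at_visit_days",
                   sex = "gender_source_value",
                   died_in_hospital = "death_during_visit"),
    measurements = c(admission_id = "visit_occurrence_id",
                     analyte = "measurement_source_value",
                     value = "value_as_number",
                     unit = "unit_source_value",
                     collected_at = "measurement_datetime"),
    diagnoses = c(admission_id = "visit_occurrence_id",
                  code = "condition_source_value",
                  vocabulary = "condition_source_vocabulary"),
    unit_stays = c(admission_id = "visit_occurrence_id",
                   unit_id = "care_site_id"),
    reference_ranges = setNames(req$reference_ranges,
                                req$reference_ranges)
  )
}

empty_violations <- function() {
  data.frame(table = character(), row = integer(),
             admission_id = character(), field = character(),
             problem = character(), stringsAsFactors = FALSE)
}

add_violation <- function(v, table, rows, ids, field, problem) {
  if (length(rows) == 0) return(v)
  rbind(v, data.frame(table = table, row = as.integer(rows),
                      admission_id = as.character(ids), field = field,
                      problem = problem, stringsAsFactors = FALSE))
}

#' Assemble and validate a cohort bundle from in-memory tables
#'
#' A cohort bundle holds the admissions, lab measurements, diagnosis
#' records, hospital-unit stays and reference ranges for one analysis run.
#' Validation enforces the structural invariants: typed columns, unique
#' admission ids, `discharge_date >= admit_date`, non-negative ages and
#' lab values, foreign keys into the admissions table (orphan rows are
#' dropped and collected into the violation report), and deduplicated
#' `(admission_id, unit_id)` pairs.
#'
#' @param admissions,measurements,diagnoses,unit_stays,reference_ranges
#'   Data frames with the canonical columns (see [read_bundle()]).
#'   Measurements/diagnoses/unit stays may be `NULL` for empty tables;
#'   `reference_ranges = NULL` falls back to [default_reference_ranges()].
#' @return A `cohort_bundle` with a `violations` data frame attached.
#' @export
cohort_bundle <- function(admissions, measurements = NULL,
                          diagnoses = NULL, unit_stays = NULL,
                          reference_ranges = NULL) {
  tables <- list(admissions = admissions,
                 measurements = measurements %||% empty_table("measurements"),
                 diagnoses = diagnoses %||% empty_table("diagnoses"),
                 unit_stays = unit_stays %||% empty_table("unit_stays"),
                 reference_ranges = reference_ranges %||%
                   default_reference_ranges())
  validate_bundle(tables)
}

empty_table <- function(name) {
  cols <- required_columns()[[name]]
  as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                stringsAsFactors = FALSE)
}

coerce_column <- function(x, type) {
  switch(type,
    character = as.character(x),
    numeric = suppressWarnings(as.numeric(x)),
    date = suppressWarnings(as.Date(as.character(x))),
    logical = {
      if (is.logical(x)) x
      else if (is.numeric(x)) x != 0
      else as.logical(toupper(as.character(x)))
    },
    x)
}

column_types <- function() {
  list(
    admissions = c(admission_id = "character", patient_id = "character",
                   institution = "character", admit_date = "date",
                   discharge_date = "date", age_at_admission = "numeric",
                   sex = "character", died_in_hospital = "logical"),
    measurements = c(admission_id = "character", analyte = "character",
                     value = "numeric", unit = "character",
                     collected_at = "character"),
    diagnoses = c(admission_id = "character", code = "character",
                  vocabulary = "character"),
    unit_stays = c(admission_id = "character", unit_id = "character"),
    reference_ranges = c(institution = "character", analyte = "character",
                         age_group = "character", low = "numeric",
                         high = "numeric", unit = "character")
  )
}

validate_bundle <- function(tables) {
  v <- empty_violations()
  types <- column_types()
  req <- required_columns()
  for (nm in bundle_tables()) {
    tab <- tables[[nm]]
    missing <- setdiff(req[[nm]], names(tab))
    if (length(missing))
      abort("table '%s' is missing required column(s): %s", nm,
            paste(missing, collapse = ", "))
    tab <- tab[req[[nm]]]
    for (col in req[[nm]]) {
      coerced <- coerce_column(tab[[col]], types[[nm]][[col]])
      bad <- which(is.na(coerced) & !is.na(tab[[col]]) &
                     tab[[col]] != "")
      if (length(bad)) {
        ids <- if ("admission_id" %in% names(tab))
          tab$admission_id[bad] else NA_character_
        v <- add_violation(v, nm, bad, ids, col, "type coercion failed")
      }
      tab[[col]] <- coerced
    }
    tables[[nm]] <- tab
  }

  adm <- tables$admissions
  dup <- which(duplicated(adm$admission_id))
  if (length(dup)) {
    v <- add_violation(v, "admissions", dup, adm$admission_id[dup],
                       "admission_id", "duplicate admission_id")
    adm <- adm[-dup, , drop = FALSE]
  }
  bad_row <- which(is.na(adm$admission_id) | is.na(adm$admit_date) |
                     is.na(adm$discharge_date) |
                     is.na(adm$age_at_admission))
  if (length(bad_row)) {
    v <- add_violation(v, "admissions", bad_row, adm$admission_id[bad_row],
                       "(row)", "missing required value")
    adm <- adm[setdiff(seq_len(nrow(adm)), bad_row), , drop = FALSE]
  }
  bad_dates <- which(adm$discharge_date < adm$admit_date)
  if (length(bad_dates)) {
    v <- add_violation(v, "admissions", bad_dates,
                       adm$admission_id[bad_dates], "discharge_date",
                       "discharge before admission")
    adm <- adm[setdiff(seq_len(nrow(adm)), bad_dates), , drop = FALSE]
  }
  bad_age <- which(adm$age_at_admission < 0)
  if (length(bad_age)) {
    v <- add_violation(v, "admissions", bad_age, adm$admission_id[bad_age],
                       "age_at_admission", "negative age")
    adm <- adm[setdiff(seq_len(nrow(adm)), bad_age), , drop = FALSE]
  }
  adm$sex[!adm$sex %in% c("female", "male")] <- "unknown"
  tables$admissions <- adm

  # foreign keys: orphan rows dropped with a violation entry each
  for (nm in c("measurements", "diagnoses", "unit_stays")) {
    tab <- tables[[nm]]
    orphan <- which(!tab$admission_id %in% adm$admission_id)
    if (length(orphan)) {
      v <- add_violation(v, nm, orphan, tab$admission_id[orphan],
                         "admission_id", "unknown admission_id")
      tab <- tab[setdiff(seq_len(nrow(tab)), orphan), , drop = FALSE]
    }
    tables[[nm]] <- tab
  }

  m <- tables$measurements
  bad_val <- which(is.na(m$value) | m$value < 0)
  if (length(bad_val)) {
    v <- add_violation(v, "measurements", bad_val,
                       m$admission_id[bad_val], "value",
                       "missing or negative value")
    m <- m[setdiff(seq_len(nrow(m)), bad_val), , drop = FALSE]
  }
  tables$measurements <- m

  dg <- tables$diagnoses
  bad_code <- which(is.na(dg$code) | dg$code == "")
  if (length(bad_code)) {
    v <- add_violation(v, "diagnoses", bad_code,
                       dg$admission_id[bad_code], "code", "empty code")
    dg <- dg[setdiff(seq_len(nrow(dg)), bad_code), , drop = FALSE]
  }
  tables$diagnoses <- dg

  us <- tables$unit_stays
  us <- us[!duplicated(us[c("admission_id", "unit_id")]), , drop = FALSE]
  tables$unit_stays <- us

  rr <- tables$reference_ranges
  if (nrow(rr) && any(rr$low >= rr$high))
    abort("reference ranges must satisfy low < high")

  rownames(tables$admissions) <- NULL
  for (nm in bundle_tables()) rownames(tables[[nm]]) <- NULL
  structure(c(tables, list(violations = v)), class = "cohort_bundle")
}

#' Read a cohort bundle from delimited-text files
#'
#' Reads the per-table CSV files of either dialect, renames columns to the
#' canonical schema and validates the result. Rows failing type coercion
#' or referencing an unknown admission are dropped and reported in the
#' bundle's `violations` table; missing files and missing required columns
#' are fatal.
#'
#' @param paths Named list/vector of file paths with elements
#'   `admissions`, `measurements`, `diagnoses`, `unit_stays` and
#'   optionally `reference_ranges`.
#' @param dialect `"flat"` or `"omop"` (ignored when `column_map` given).
#' @param column_map Optional explicit column map as from
#'   [dialect_column_map()].
#' @param sep Field separator (default comma).
#' @return A validated `cohort_bundle`.
#' @export
read_bundle <- function(paths, dialect = c("flat", "omop"),
                        column_map = NULL, sep = ",") {
  map <- column_map %||% dialect_column_map(dialect)
  tables <- list()
  for (nm in bundle_tables()) {
    path <- paths[[nm]]
    if (is.null(path)) {
      if (nm == "reference_ranges") {
        tables[[nm]] <- default_reference_ranges()
        next
      }
      abort("no path supplied for table '%s'", nm)
    }
    if (!file.exists(path)) abort("file not found: %s", path)
    raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
    m <- map[[nm]]
    missing <- setdiff(unname(m), names(raw))
    if (length(missing))
      abort("file '%s' is missing required column(s): %s", path,
            paste(missing, collapse = ", "))
    tab <- raw[unname(m)]
    names(tab) <- names(m)
    tables[[nm]] <- tab
  }
  validate_bundle(tables)
}

#' Write a cohort bundle to delimited-text files
#'
#' Inverse of [read_bundle()]: writes one CSV per table in the requested
#' dialect. Reading the files back reproduces the bundle field-for-field.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @param dialect `"flat"` or `"omop"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, dir, dialect = c("flat", "omop")) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  map <- dialect_column_map(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in bundle_tables()) {
    tab <- bundle[[nm]]
    m <- map[[nm]]
    out <- tab[names(m)]
    names(out) <- unname(m)
    path <- file.path(dir, paste0(nm, ".csv"))
    write.csv(out, path, row.names = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Write the violation report as JSON lines
#'
#' One JSON object per dropped/flagged row, machine-readable for audit.
#'
#' @param bundle A `cohort_bundle`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_violations <- function(bundle, path) {
  v <- bundle$violations
  lines <- vapply(seq_len(nrow(v)), function(i) {
    as.character(jsonlite::toJSON(as.list(v[i, ]), auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  for (nm in bundle_tables())
    cat(sprintf("  %-17s %6d rows\n", nm, nrow(x[[nm]])))
  inst <- table(x$admissions$institution)
  if (length(inst))
    cat("  institutions:", paste(sprintf("%s (%d)", names(inst), inst),
                                 collapse = ", "), "\n")
  cat(sprintf("  violations: %d\n", nrow(x$violations)))
  invisible(x)
}
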
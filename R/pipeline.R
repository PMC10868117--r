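# End-to-end pipeline: simulate -> label -> concord -> associate ->
# report, with delimited-text artifacts and a JSON run manifest.

stage_names <- function() {
  c("simulate", "label", "concord", "associate", "report")
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[labconcord] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Runs the selected stages in order, writing each stage's artifact files
#' to `out_dir` and a JSON run manifest at the end. Stages read the
#' outputs of earlier stages from `out_dir` when those stages are not
#' selected, so a pre-generated bundle can be labeled without
#' re-simulating. A stage failure aborts with partial outputs retained
#' and the manifest recording the failure point.
#'
#' Artifacts: the bundle tables and truth ledger (`simulate`);
#' `labels.csv` (`label`); `prevalence.csv`, `metrics.csv`,
#' `metric_summary.csv`, `unit_points.csv`, `unit_rho.csv` (`concord`);
#' `or_table.csv` (`associate`); `table3.csv` and `manifest.json`
#' (`report`).
#'
#' @param config A [simulation_config()], or the name of a
#'   [scenario_presets()] entry.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of simulate/label/concord/associate/report.
#' @param seed RNG seed (default the config's).
#' @param nAGQ Quadrature nodes for the association stage.
#' @param verbose Log per-stage row counts via `message()`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, stages = stage_names(),
                         seed = NULL, nAGQ = 15, verbose = TRUE) {
  if (is.character(config) && length(config) == 1)
    config <- scenario_presets()[[match.arg(config,
                                            names(scenario_presets()))]]
  stopifnot(inherits(config, "simulation_config"))
  stages <- match.arg(stages, stage_names(), several.ok = TRUE)
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package_version = as.character(packageVersion("labconcord")),
    seed = seed,
    config_hash = hash_object(config[setdiff(names(config),
                                             c("definitions"))]),
    stages = stages, row_counts = list(), warnings = character(),
    status = "running")
  fail <- function(stage, e) {
    manifest$status <<- sprintf("failed at stage '%s': %s", stage,
                                conditionMessage(e))
    write_manifest(manifest, out_dir)
    stop(e)
  }

  res <- list(config = config)

  if ("simulate" %in% stages) {
    tryCatch({
      sim <- generate_cohort(config, seed = seed)
      res$bundle <- sim$bundle
      res$ledger <- sim$ledger
      write_bundle(sim$bundle, out_dir)
      write.csv(sim$ledger, file.path(out_dir, "truth_ledger.csv"),
                row.names = FALSE)
      write_violations(sim$bundle, file.path(out_dir, "violations.jsonl"))
      manifest$row_counts$admissions <- nrow(sim$bundle$admissions)
      manifest$row_counts$measurements <- nrow(sim$bundle$measurements)
      manifest$row_counts$diagnoses <- nrow(sim$bundle$diagnoses)
      log_msg(verbose, "simulate: %d admissions, %d measurements",
              nrow(sim$bundle$admissions), nrow(sim$bundle$measurements))
    }, error = function(e) fail("simulate", e))
  }

  need_bundle <- function() {
    res$bundle %||% read_bundle(list(
      admissions = file.path(out_dir, "admissions.csv"),
      measurements = file.path(out_dir, "measurements.csv"),
      diagnoses = file.path(out_dir, "diagnoses.csv"),
      unit_stays = file.path(out_dir, "unit_stays.csv"),
      reference_ranges = file.path(out_dir, "reference_ranges.csv")))
  }

  if ("label" %in% stages) {
    tryCatch({
      res$bundle <- need_bundle()
      res$labels <- label_cohort(res$bundle, config$definitions)
      write.csv(res$labels, file.path(out_dir, "labels.csv"),
                row.names = FALSE)
      manifest$row_counts$labels <- nrow(res$labels)
      log_msg(verbose, "label: %d label rows", nrow(res$labels))
    }, error = function(e) fail("label", e))
  }

  need_labels <- function() {
    res$labels %||% {
      l <- read.csv(file.path(out_dir, "labels.csv"),
                    stringsAsFactors = FALSE)
      class(l) <- c("admission_labels", "data.frame")
      l
    }
  }

  if ("concord" %in% stages) {
    tryCatch({
      res$bundle <- need_bundle()
      labels <- need_labels()
      res$prevalence <- prevalence_table(labels)
      res$metrics <- concordance_metrics(labels)
      summ <- do.call(rbind, lapply(
        c("kappa", "sensitivity", "specificity"),
        function(m) summarize_metrics(res$metrics, m)))
      res$metric_summary <- summ
      uc <- unit_concordance(labels, res$bundle$unit_stays)
      res$unit_points <- uc$points
      res$unit_rho <- uc$rho
      write.csv(res$prevalence, file.path(out_dir, "prevalence.csv"),
                row.names = FALSE)
      write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                row.names = FALSE)
      write.csv(summ, file.path(out_dir, "metric_summary.csv"),
                row.names = FALSE)
      write.csv(uc$points, file.path(out_dir, "unit_points.csv"),
                row.names = FALSE)
      write.csv(uc$rho, file.path(out_dir, "unit_rho.csv"),
                row.names = FALSE)
      manifest$row_counts$metrics <- nrow(res$metrics)
      log_msg(verbose, "concord: %d metric rows, %d unit points",
              nrow(res$metrics), nrow(uc$points))
    }, error = function(e) fail("concord", e))
  }

  if ("associate" %in% stages) {
    tryCatch({
      labels <- need_labels()
      res$or_table <- or_by_institution(labels, nAGQ = nAGQ)
      write.csv(res$or_table, file.path(out_dir, "or_table.csv"),
                row.names = FALSE)
      manifest$row_counts$or_estimates <- nrow(res$or_table)
      nc <- sum(!res$or_table$converged)
      if (nc > 0)
        manifest$warnings <- c(manifest$warnings,
                               sprintf("%d OR fits did not converge", nc))
      log_msg(verbose, "associate: %d OR estimates (%d not converged)",
              nrow(res$or_table), nc)
    }, error = function(e) fail("associate", e))
  }

  if ("report" %in% stages) {
    tryCatch({
      prev <- res$prevalence %||%
        read.csv(file.path(out_dir, "prevalence.csv"),
                 stringsAsFactors = FALSE)
      ors <- res$or_table %||%
        read.csv(file.path(out_dir, "or_table.csv"),
                 stringsAsFactors = FALSE)
      res$table3 <- render_table3(prev, ors)
      write.csv(res$table3, file.path(out_dir, "table3.csv"),
                row.names = FALSE)
      log_msg(verbose, "report: %d rendered rows", nrow(res$table3))
    }, error = function(e) fail("report", e))
  }

  manifest$status <- "ok"
  res$manifest <- manifest
  write_manifest(manifest, out_dir)
  invisible(res)
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)   # atomic on the same filesystem
  invisible(path)
}

#' Render the prevalence-plus-OR summary table
#'
#' One row per severity x outcome, with a `"count (pct%)"` cell per
#' cohort and an `"OR (low, high)"` cell from the institution odds-ratio
#' table. Pure formatting: every number is re-derivable from the stage
#' artifacts. A missing OR row renders as an empty cell with a warning.
#'
#' @param prevalence Output of [prevalence_table()].
#' @param or_table Output of [or_by_institution()].
#' @return Data frame with severity, outcome, one column per cohort and
#'   an odds-ratio column.
#' @export
render_table3 <- function(prevalence, or_table) {
  cohorts <- sort(unique(prevalence$cohort))
  sevs <- intersect(c(severity_levels(), "diagnosis"),
                    unique(prevalence$severity))
  rows <- list()
  for (sev in sevs) {
    for (oc in sort(unique(prevalence$outcome))) {
      row <- list(severity = sev, outcome = oc)
      for (coh in cohorts) {
        cell <- prevalence[prevalence$severity == sev &
                             prevalence$outcome == oc &
                             prevalence$cohort == coh, , drop = FALSE]
        row[[coh]] <- if (nrow(cell) == 1)
          render_count_pct(cell$count, cell$n_admissions) else ""
      }
      orr <- or_table[or_table$label_type == sev &
                        or_table$outcome == oc, , drop = FALSE]
      row$odds_ratio <- if (nrow(orr) == 1 && !is.na(orr$or)) {
        sprintf("%.1f (%.1f,%.1f)", orr$or, orr$ci_low, orr$ci_high)
      } else {
        warning(sprintf("no odds ratio for %s / %s", sev, oc),
                call. = FALSE)
        ""
      }
      rows[[length(rows) + 1]] <- as.data.frame(row,
                                                stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
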
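#' Full-run configuration
#'
#' @param cohort a [cohort_config()] for a synthetic run, or a list
#'   `list(exam_path =, reading_path =)` pointing at user data.
#' @param thresholds triage thresholds to evaluate (subset of 1..9).
#' @param margin non-inferiority margin.
#' @param alpha overall two-sided error rate.
#' @param n_comparisons Bonferroni divisor; `NULL` means the number of
#'   thresholds evaluated.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; overrides the cohort config's seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), thresholds = 1:9,
                       margin = 0.05, alpha = 0.05, n_comparisons = NULL,
                       out_dir = tempfile("mammotriage_run"),
                       seed = NULL) {
  if (!all(thresholds %in% 1:9))
    mt_abort("thresholds must be a subset of 1..9", "mt_config_error")
  if (margin <= 0) mt_abort("margin must be > 0", "mt_config_error")
  structure(list(cohort = cohort, thresholds = as.integer(thresholds),
                 margin = margin, alpha = alpha,
                 n_comparisons = n_comparisons, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Configuration to tables: obtains a reading dataset (generated from a
#' cohort config, or loaded from user CSVs), assigns AI categories by
#' decile calibration when only raw scores are present, runs the triage
#' threshold sweep, compares all pre-selection scenarios against the
#' original reading, and writes `exams.csv`, `readings.csv`,
#' `tradeoff.csv`, `mrmc.csv`, `roc_curves.csv` and `manifest.json` to
#' the output directory. Identical configuration and seed give
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return The run manifest (named list), invisibly also written as
#'   JSON.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$out_dir, 2) != 0)
    mt_abort(paste0("output directory not writable: ", config$out_dir),
             "mt_config_error")

  if (inherits(config$cohort, "cohort_config")) {
    cc <- config$cohort
    if (!is.null(config$seed)) cc$seed <- as.integer(config$seed)
    log_stage("simulate", "generating cohort (seed %d)", cc$seed)
    ds <- generate_split_plot(cc)
    synthetic <- TRUE
  } else {
    log_stage("load", "reading %s", config$cohort$exam_path)
    ds <- load_dataset(config$cohort$exam_path, config$cohort$reading_path)
    synthetic <- FALSE
  }
  if (any(is.na(ds$exams$ai_category))) {
    log_stage("calibrate", "assigning AI categories from raw scores")
    normals <- ds$exams$raw_score[ds$exams$truth == "normal" &
                                    !is.na(ds$exams$raw_score)]
    map <- calibrate(normals)
    na_cat <- is.na(ds$exams$ai_category)
    ds$exams$ai_category[na_cat] <-
      apply_calibration(map, ds$exams$raw_score[na_cat])
  }
  log_stage("simulate", "%d exams, %d readings", nrow(ds$exams),
            nrow(ds$readings))

  paths <- file.path(config$out_dir,
                     c(exams = "exams.csv", readings = "readings.csv",
                       tradeoff = "tradeoff.csv", mrmc = "mrmc.csv",
                       curves = "roc_curves.csv",
                       manifest = "manifest.json"))
  names(paths) <- c("exams", "readings", "tradeoff", "mrmc", "curves",
                    "manifest")
  write_dataset(ds, paths[["exams"]], paths[["readings"]])

  sweep_tab <- triage_sweep(ds, config$thresholds)
  utils::write.csv(sweep_tab, paths[["tradeoff"]], row.names = FALSE)
  log_stage("triage", "%d threshold(s) evaluated", nrow(sweep_tab))

  mrmc_section <- nrow(ds$readings) > 0
  if (mrmc_section) {
    ncmp <- if (is.null(config$n_comparisons)) length(config$thresholds)
            else config$n_comparisons
    cmp <- compare_scenarios(ds, thresholds = config$thresholds,
                             margin = config$margin, alpha = config$alpha,
                             n_comparisons = ncmp)
    utils::write.csv(cmp$results, paths[["mrmc"]], row.names = FALSE)
    utils::write.csv(cmp$curves, paths[["curves"]], row.names = FALSE)
    log_stage("mrmc", "original AUC %.4f over %d scenario(s)",
              cmp$results$auc[1], nrow(cmp$results) - 1)
  } else {
    log_stage("mrmc", "no readings; MRMC section skipped")
    cmp <- NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mammotriage")),
    r_version = R.version.string,
    seed = if (synthetic) config$cohort$seed else config$seed,
    synthetic = synthetic,
    thresholds = config$thresholds,
    margin = config$margin,
    alpha = config$alpha,
    n_comparisons = if (is.null(config$n_comparisons))
      length(config$thresholds) else config$n_comparisons,
    n_exams = nrow(ds$exams),
    n_readings = nrow(ds$readings),
    class_counts = as.list(table(ds$exams$truth)),
    mrmc_available = mrmc_section,
    paths = as.list(paths)
  )
  if (synthetic) manifest$seed <- if (!is.null(config$seed))
    as.integer(config$seed) else config$cohort$seed
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable run report
#'
#' Renders the per-threshold trade-off and non-inferiority verdicts of a
#' completed run as a markdown table.
#'
#' @param manifest manifest list as returned by [run_full()], or the
#'   path to a `manifest.json`.
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
run_report <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  paths <- manifest$paths
  if (!file.exists(paths$tradeoff))
    mt_abort("run outputs missing; re-run the pipeline", "mt_report_error")
  sweep_tab <- utils::read.csv(paths$tradeoff)
  mrmc_tab <- if (isTRUE(manifest$mrmc_available) &&
                  file.exists(paths$mrmc))
    utils::read.csv(paths$mrmc) else NULL

  lines <- c(sprintf("# Triage run: %d exams, %d readings",
                     manifest$n_exams, manifest$n_readings), "")
  header <- "| threshold | workload reduction (screening) | cancers excluded | benigns excluded | delta AUC | noninferior |"
  lines <- c(lines, header,
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(sweep_tab))) {
    t <- sweep_tab$threshold[i]
    if (!is.null(mrmc_tab)) {
      row <- mrmc_tab[!is.na(mrmc_tab$threshold) & mrmc_tab$threshold == t, ]
      dtxt <- sprintf("%+.4f [%+.4f, %+.4f]", row$delta, row$ci_low,
                      row$ci_high)
      ntxt <- ifelse(row$noninferior, "yes", "NO")
    } else {
      dtxt <- "-"; ntxt <- "-"
    }
    lines <- c(lines, sprintf(
      "| %d | %.1f%% | %.1f%% | %.1f%% | %s | %s |", t,
      100 * sweep_tab$workload_reduction_screening[i],
      sweep_tab$pct_cancer_excluded[i], sweep_tab$pct_benign_excluded[i],
      dtxt, ntxt))
  }
  if (is.null(mrmc_tab))
    lines <- c(lines, "", "MRMC section absent (no readings).")
  else
    lines <- c(lines, "", sprintf(
      "Original reader-averaged AUC: %.4f (margin %.2f, Bonferroni n = %d).",
      mrmc_tab$auc[is.na(mrmc_tab$threshold)][1], manifest$margin,
      manifest$n_comparisons))
  cat(lines, sep = "\n")
  invisible(lines)
}
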
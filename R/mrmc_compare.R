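#' Non-inferiority test for an AUC difference
#'
#' Normal-theory two-sided confidence interval for the AUC difference
#' at Bonferroni-adjusted level `1 - alpha / n_comparisons`.
#' Non-inferiority of the scenario is declared when the lower CI bound
#' exceeds `-margin`; with `require_positive_delta = TRUE` the stricter
#' rule additionally requires `delta > 0`.
#'
#' @param delta AUC difference (scenario minus baseline).
#' @param var_delta variance of the difference (>= 0).
#' @param margin non-inferiority margin (> 0; default 0.05 AUC).
#' @param n_comparisons Bonferroni divisor (>= 1).
#' @param alpha overall two-sided error rate (default 0.05).
#' @param require_positive_delta also require `delta > 0` (off by
#'   default).
#' @return List with `delta`, `ci_low`, `ci_high`, `level`,
#'   `noninferior`.
#' @export
noninferiority_test <- function(delta, var_delta, margin = 0.05,
                                n_comparisons = 1, alpha = 0.05,
                                require_positive_delta = FALSE) {
  if (is.na(var_delta) || var_delta < 0)
    mt_abort("var_delta must be non-negative", "mt_argument_error")
  if (margin <= 0 || n_comparisons < 1)
    mt_abort("margin must be > 0 and n_comparisons >= 1",
             "mt_argument_error")
  level <- 1 - alpha / n_comparisons
  z <- stats::qnorm(1 - (alpha / n_comparisons) / 2)
  se <- sqrt(var_delta)
  ci <- c(delta - z * se, delta + z * se)
  ni <- ci[1] > -margin
  if (require_positive_delta) ni <- ni && delta > 0
  list(delta = delta, ci_low = ci[1], ci_high = ci[2], level = level,
       noninferior = ni)
}

#' Compare the original reading with all pre-selection scenarios
#'
#' For each triage threshold, excluded exams have all their radiologist
#' scores reassigned to the scale minimum, the paired reader-averaged
#' AUC difference against the original reading is estimated with its
#' U-statistic variance, and a Bonferroni-corrected non-inferiority
#' test is performed. Reader-averaged ROC curves are returned for every
#' scenario (original included) for plotting.
#'
#' @param ds a `reading_dataset` with `ai_category` on every exam.
#' @param thresholds integer subset of 1..9 (default all nine).
#' @param margin non-inferiority margin (default 0.05).
#' @param alpha overall two-sided error rate (default 0.05).
#' @param n_comparisons Bonferroni divisor; defaults to the number of
#'   thresholds evaluated.
#' @param grid_size grid for [average_curves()].
#' @return List of class `mrmc_comparison` with `results` (one row per
#'   scenario: `scenario`, `threshold`, `auc`, `var`, `delta`,
#'   `ci_low`, `ci_high`, `noninferior`) and `curves` (long data.frame
#'   `scenario`, `fpf`, `tpf`).
#' @export
compare_scenarios <- function(ds, thresholds = 1:9, margin = 0.05,
                              alpha = 0.05,
                              n_comparisons = length(thresholds),
                              grid_size = 1001L) {
  stopifnot(inherits(ds, "reading_dataset"))
  base <- mrmc_auc(ds)
  rows <- list(data.frame(scenario = "original", threshold = NA_integer_,
                          auc = base$auc, var = base$var,
                          delta = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, noninferior = NA))
  curves <- list(curve_table(ds, ds$readings, "original", grid_size))
  for (t in thresholds) {
    part <- triage_partition(ds$exams, t)
    scen_readings <- reassign_scores(ds, part$excluded_exam_ids)
    d <- mrmc_delta(ds, scen_readings)
    ni <- noninferiority_test(d$delta, d$var_delta, margin = margin,
                              n_comparisons = n_comparisons, alpha = alpha)
    lab <- paste0("threshold_", t)
    rows[[length(rows) + 1L]] <-
      data.frame(scenario = lab, threshold = as.integer(t),
                 auc = d$auc_scenario, var = d$var_scenario,
                 delta = d$delta, ci_low = ni$ci_low,
                 ci_high = ni$ci_high, noninferior = ni$noninferior)
    curves[[length(curves) + 1L]] <-
      curve_table(ds, scen_readings, lab, grid_size)
  }
  structure(list(results = do.call(rbind, rows),
                 curves = do.call(rbind, curves),
                 margin = margin, alpha = alpha,
                 n_comparisons = n_comparisons),
            class = "mrmc_comparison")
}

# reader-averaged ROC vertices of one scenario as a long table
curve_table <- function(ds, readings, label, grid_size) {
  units <- build_units(ds, readings)
  curves <- list()
  for (u in units) {
    if (u$n1 == 0 || u$n0 == 0) next
    rd <- readings[readings$reader_id == u$reader, ]
    ex <- ds$exams[match(rd$exam_id, ds$exams$exam_id), ]
    in_block <- ex$study_id == u$block
    curves[[length(curves) + 1L]] <-
      reader_curve(rd$score[in_block], ex$truth[in_block],
                   reader_id = paste(u$reader, u$block))
  }
  av <- average_curves(curves, grid_size = grid_size)
  data.frame(scenario = label, fpf = av$points$fpf, tpf = av$points$tpf,
             stringsAsFactors = FALSE)
}

#' @export
print.mrmc_comparison <- function(x, ...) {
  cat("<mrmc_comparison>\n")
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}
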
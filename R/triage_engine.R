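#' Decile calibration of a continuous suspicion score on normal exams
#'
#' Computes the nine cutpoints that map a continuous AI output to the
#' integer categories 1--10 such that each category holds approximately
#' 10% of the normal exams used for calibration. Cutpoints are the
#' 10%, 20%, ..., 90% empirical inverse-CDF (type-1) quantiles of the
#' normal raw scores; [apply_calibration()] assigns category `k` to
#' scores in `(cut[k-1], cut[k]]`, so boundary scores fall in the lower
#' category.
#'
#' @param raw_scores_of_normals numeric vector with at least 10 distinct
#'   values.
#' @return Object of class `calibration_map` with field `cutpoints`
#'   (9 strictly ascending thresholds).
#' @export
calibrate <- function(raw_scores_of_normals) {
  x <- raw_scores_of_normals[!is.na(raw_scores_of_normals)]
  if (length(unique(x)) < 10)
    mt_abort("calibration requires at least 10 distinct raw scores",
             "mt_calibration_error")
  # type-1 (inverse empirical CDF) quantiles at k/10, with the order
  # statistic index ceiling(n*k/10) computed in exact integer arithmetic
  # (quantile(..., type = 1) can misplace the index through floating-
  # point representation of the probabilities)
  xs <- sort(x)
  n <- length(xs)
  nk <- as.numeric(n) * (1:9)
  idx <- nk %/% 10 + (nk %% 10 > 0)
  cut <- xs[idx]
  if (any(diff(cut) <= 0))
    mt_abort("calibration cutpoints are not strictly ascending (raw scores too discrete)",
             "mt_calibration_error")
  structure(list(cutpoints = cut), class = "calibration_map")
}

#' Apply a calibration map to raw scores
#'
#' @param map a `calibration_map`.
#' @param raw_scores numeric vector.
#' @return Integer categories in 1--10.
#' @export
apply_calibration <- function(map, raw_scores) {
  stopifnot(inherits(map, "calibration_map"))
  # (cut[k-1], cut[k]] -> k; right-closed intervals put ties in the
  # lower category, keeping per-category counts <= ceiling(n/10)
  as.integer(findInterval(raw_scores, map$cutpoints, left.open = TRUE)) + 1L
}

#' Partition exams into excluded and pre-selected groups at one threshold
#'
#' Exams with `ai_category <= threshold` are excluded from reading
#' (automatically reported normal); exams with a higher category are
#' pre-selected for radiologist evaluation. Two workload figures are
#' reported: `workload_reduction_screening`, the excluded fraction of
#' NORMAL exams (a screening load is dominated by normals, so this is
#' the operative screening quantity), and `workload_reduction_sample`,
#' the excluded fraction of the analyzed (enriched) sample.
#'
#' @param exams exam table (all rows must have `ai_category`).
#' @param threshold integer in 1--9.
#' @return Object of class `triage_result`.
#' @export
triage_partition <- function(exams, threshold) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold != as.integer(threshold) || threshold < 1 || threshold > 9)
    mt_abort("threshold must be a single integer in 1..9",
             "mt_argument_error")
  if (any(is.na(exams$ai_category)))
    mt_abort("all exams need ai_category for triage (calibrate first)",
             "mt_argument_error")
  excl <- exams$ai_category <= threshold
  frac <- function(cls) {
    n <- sum(exams$truth == cls)
    if (n == 0) 0 else sum(excl & exams$truth == cls) / n
  }
  by_class <- c(normal = frac("normal"), benign = frac("benign"),
                cancer = frac("cancer"))
  structure(list(
    threshold = as.integer(threshold),
    excluded_exam_ids = exams$exam_id[excl],
    preselected_exam_ids = exams$exam_id[!excl],
    excl_fraction_by_class = by_class,
    workload_reduction_screening = by_class[["normal"]],
    workload_reduction_sample = if (nrow(exams) == 0) 0 else mean(excl)
  ), class = "triage_result")
}

#' Reassign radiologist scores of excluded exams to the scale minimum
#'
#' Implements the pre-selection scenario: every reading of an excluded
#' exam is set to the lowest possible value of its own declared scale;
#' readings of pre-selected exams are returned bit-identical (invariance
#' of reader behaviour is assumed).
#'
#' @param ds a `reading_dataset`.
#' @param excluded_exam_ids character vector of exam ids to exclude.
#' @return The reading table with reassigned scores.
#' @export
reassign_scores <- function(ds, excluded_exam_ids) {
  stopifnot(inherits(ds, "reading_dataset"))
  unknown <- setdiff(excluded_exam_ids, ds$exams$exam_id)
  if (length(unknown) > 0)
    mt_abort(paste0("excluded ids not in dataset: ",
                    paste(utils::head(unknown, 5), collapse = ", ")),
             "mt_integrity_error")
  readings <- ds$readings
  hit <- readings$exam_id %in% excluded_exam_ids
  readings$score[hit] <- readings$scale_min[hit]
  readings
}

#' Threshold sweep: triage trade-off table for thresholds 1..9
#'
#' @param ds a `reading_dataset` (or a bare exam table).
#' @param thresholds integer vector, subset of 1..9.
#' @return data.frame with columns `threshold`, `n_excluded`,
#'   `pct_normal_excluded`, `pct_benign_excluded`, `pct_cancer_excluded`
#'   (percent), `workload_reduction_screening`,
#'   `workload_reduction_sample` (fractions in `[0, 1]`).
#' @export
triage_sweep <- function(ds, thresholds = 1:9) {
  exams <- if (inherits(ds, "reading_dataset")) ds$exams else ds
  rows <- lapply(thresholds, function(t) {
    p <- triage_partition(exams, t)
    data.frame(threshold = t,
               n_excluded = length(p$excluded_exam_ids),
               pct_normal_excluded = 100 * p$excl_fraction_by_class[["normal"]],
               pct_benign_excluded = 100 * p$excl_fraction_by_class[["benign"]],
               pct_cancer_excluded = 100 * p$excl_fraction_by_class[["cancer"]],
               workload_reduction_screening = p$workload_reduction_screening,
               workload_reduction_sample = p$workload_reduction_sample)
  })
  do.call(rbind, rows)
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf(
    "<triage_result> threshold %d: %d excluded / %d pre-selected\n",
    x$threshold, length(x$excluded_exam_ids),
    length(x$preselected_exam_ids)))
  cat(sprintf("  excluded: %.1f%% of normals, %.1f%% of benigns, %.1f%% of cancers\n",
              100 * x$excl_fraction_by_class[["normal"]],
              100 * x$excl_fraction_by_class[["benign"]],
              100 * x$excl_fraction_by_class[["cancer"]]))
  invisible(x)
}
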
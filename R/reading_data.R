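#' Reading data model: exams, radiologist readings, score scales
#'
#' A `reading_dataset` bundles three tables:
#' \describe{
#'   \item{exams}{one row per exam: `exam_id`, `study_id`, `truth`
#'     (one of `"normal"`, `"benign"`, `"cancer"`), `ai_category`
#'     (integer 1--10, may be `NA` if `raw_score` is present) and
#'     `raw_score` (continuous suspicion, may be `NA`).}
#'   \item{readings}{one row per radiologist interpretation: `exam_id`,
#'     `reader_id`, `study_id`, `score`, `scale_min`, `scale_max`.}
#'   \item{scales}{the distinct score scales referenced by the readings:
#'     `scale_id`, `scale_min`, `scale_max`.}
#' }
#' Ground truth for all ROC computations is binary: cancer exams are
#' positives; benign and normal exams are both negatives. Exams read by
#' no reader are allowed (they still count in triage statistics) but are
#' ignored by ROC/MRMC computations.
#'
#' @param exams data.frame of exams (see above).
#' @param readings data.frame of readings (see above). May have zero rows.
#' @name reading_dataset
NULL

TRUTH_LEVELS <- c("normal", "benign", "cancer")

#' Construct and validate a reading dataset
#'
#' @rdname reading_dataset
#' @return An object of class `reading_dataset`.
#' @export
reading_dataset <- function(exams, readings) {
  exams <- validate_exam_table(exams)
  readings <- validate_reading_table(readings, exams)
  scales <- derive_scales(readings)
  structure(list(exams = exams, readings = readings, scales = scales),
            class = "reading_dataset")
}

validate_exam_table <- function(exams) {
  need <- c("exam_id", "study_id", "truth")
  miss <- setdiff(need, names(exams))
  if (length(miss) > 0)
    mt_abort(paste0("exam table is missing column(s): ",
                    paste(miss, collapse = ", ")), "mt_format_error")
  if (!"ai_category" %in% names(exams)) exams$ai_category <- NA_integer_
  if (!"raw_score" %in% names(exams)) exams$raw_score <- NA_real_
  exams$exam_id <- as.character(exams$exam_id)
  exams$study_id <- as.character(exams$study_id)
  exams$truth <- as.character(exams$truth)
  exams$raw_score <- as.numeric(exams$raw_score)

  bad <- !exams$truth %in% TRUTH_LEVELS
  if (any(bad))
    mt_abort(paste0("unknown truth label(s): ",
                    paste(unique(exams$truth[bad]), collapse = ", ")),
             "mt_validation_error")
  if (anyDuplicated(exams$exam_id))
    mt_abort("duplicate exam_id values in exam table", "mt_validation_error")

  cat_ok <- is.na(exams$ai_category) |
    (exams$ai_category == as.integer(exams$ai_category) &
       exams$ai_category >= 1 & exams$ai_category <= 10)
  if (!all(cat_ok))
    mt_abort(paste0("ai_category must be an integer in [1, 10]; offending ",
                    "exam(s): ",
                    paste(utils::head(exams$exam_id[!cat_ok], 5),
                          collapse = ", ")),
             "mt_validation_error")
  neither <- is.na(exams$ai_category) & is.na(exams$raw_score)
  if (any(neither))
    mt_abort(paste0("each exam needs ai_category or raw_score; missing for: ",
                    paste(utils::head(exams$exam_id[neither], 5),
                          collapse = ", ")),
             "mt_validation_error")
  exams$ai_category <- as.integer(exams$ai_category)
  exams[, c("exam_id", "study_id", "truth", "ai_category", "raw_score")]
}

validate_reading_table <- function(readings, exams) {
  need <- c("exam_id", "reader_id", "study_id", "score",
            "scale_min", "scale_max")
  if (is.null(readings) || nrow(readings) == 0) {
    readings <- data.frame(exam_id = character(), reader_id = character(),
                           study_id = character(), score = numeric(),
                           scale_min = numeric(), scale_max = numeric(),
                           stringsAsFactors = FALSE)
    return(readings)
  }
  miss <- setdiff(need, names(readings))
  if (length(miss) > 0)
    mt_abort(paste0("reading table is missing column(s): ",
                    paste(miss, collapse = ", ")), "mt_format_error")
  readings$exam_id <- as.character(readings$exam_id)
  readings$reader_id <- as.character(readings$reader_id)
  readings$study_id <- as.character(readings$study_id)

  unknown <- !readings$exam_id %in% exams$exam_id
  if (any(unknown))
    mt_abort(paste0("reading(s) reference unknown exam(s): ",
                    paste(utils::head(unique(readings$exam_id[unknown]), 5),
                          collapse = ", ")),
             "mt_integrity_error")
  if (any(readings$scale_min >= readings$scale_max))
    mt_abort("scale_min must be strictly less than scale_max",
             "mt_validation_error")
  off <- readings$score < readings$scale_min |
    readings$score > readings$scale_max
  if (any(off))
    mt_abort(paste0("score outside declared scale at row(s): ",
                    paste(utils::head(which(off), 10), collapse = ", ")),
             "mt_validation_error")
  key <- paste(readings$exam_id, readings$reader_id, sep = "\r")
  if (anyDuplicated(key))
    mt_abort("duplicate (exam_id, reader_id) pairs in reading table",
             "mt_validation_error")
  readings[, need]
}

derive_scales <- function(readings) {
  sc <- unique(readings[, c("scale_min", "scale_max"), drop = FALSE])
  if (nrow(sc) == 0)
    return(data.frame(scale_id = character(), scale_min = numeric(),
                      scale_max = numeric(), stringsAsFactors = FALSE))
  sc <- sc[order(sc$scale_min, sc$scale_max), , drop = FALSE]
  data.frame(scale_id = paste0("scale", seq_len(nrow(sc))),
             scale_min = sc$scale_min, scale_max = sc$scale_max,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Load a reading dataset from CSV files
#'
#' Reads the `exams.csv` / `readings.csv` contract (UTF-8,
#' comma-separated, header row required) and returns a validated
#' [reading_dataset()].
#'
#' @param exam_path path to the exam CSV.
#' @param reading_path path to the reading CSV; may name an empty (header
#'   only) file.
#' @return A `reading_dataset`.
#' @export
load_dataset <- function(exam_path, reading_path) {
  for (p in c(exam_path, reading_path))
    if (!file.exists(p))
      mt_abort(paste0("file not found: ", p), "mt_format_error")
  exams <- utils::read.csv(exam_path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  readings <- utils::read.csv(reading_path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
  reading_dataset(exams, readings)
}

#' Write a reading dataset to CSV files
#'
#' Inverse of [load_dataset()]: the written files round-trip to the same
#' rows (up to column order).
#'
#' @param ds a `reading_dataset`.
#' @param exam_path,reading_path output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_dataset <- function(ds, exam_path, reading_path) {
  stopifnot(inherits(ds, "reading_dataset"))
  utils::write.csv(ds$exams, exam_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(ds$readings, reading_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(exam_path, reading_path))
}

#' Binary ground truth for ROC analysis
#'
#' Cancer exams are positives; benign and normal exams are negatives.
#'
#' @param truth character vector of truth labels.
#' @return Logical vector, `TRUE` for cancer.
#' @export
binary_truth <- function(truth) {
  bad <- !truth %in% TRUTH_LEVELS
  if (any(bad))
    mt_abort(paste0("unknown truth label(s): ",
                    paste(unique(truth[bad]), collapse = ", ")),
             "mt_validation_error")
  truth == "cancer"
}

#' Per-block design summary
#'
#' Reports, for every study block, the number of readers, the case mix by
#' ground-truth class, the number of interpretations, and whether the
#' block is fully crossed (every reader of the block read every exam of
#' the block).
#'
#' @param ds a `reading_dataset`.
#' @return data.frame with one row per study block.
#' @export
design_summary <- function(ds) {
  stopifnot(inherits(ds, "reading_dataset"))
  blocks <- sort(unique(ds$exams$study_id))
  rows <- lapply(blocks, function(b) {
    ex <- ds$exams[ds$exams$study_id == b, ]
    rd <- ds$readings[ds$readings$study_id == b, ]
    readers <- unique(rd$reader_id)
    n_cells <- length(readers) * nrow(ex)
    crossed <- if (n_cells == 0) {
      FALSE
    } else {
      # fully crossed iff each reader read each block exam exactly once
      nrow(rd) == n_cells && all(rd$exam_id %in% ex$exam_id)
    }
    data.frame(study_id = b,
               n_readers = length(readers),
               n_normal = sum(ex$truth == "normal"),
               n_benign = sum(ex$truth == "benign"),
               n_cancer = sum(ex$truth == "cancer"),
               n_readings = nrow(rd),
               fully_crossed = crossed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reader-by-exam incidence matrix
#'
#' @param ds a `reading_dataset`.
#' @return 0/1 matrix, readers in rows, exams in columns.
#' @export
incidence_matrix <- function(ds) {
  stopifnot(inherits(ds, "reading_dataset"))
  readers <- sort(unique(ds$readings$reader_id))
  exams <- ds$exams$exam_id
  m <- matrix(0L, nrow = length(readers), ncol = length(exams),
              dimnames = list(readers, exams))
  if (nrow(ds$readings) > 0)
    m[cbind(ds$readings$reader_id, ds$readings$exam_id)] <- 1L
  m
}

#' @export
print.reading_dataset <- function(x, ...) {
  cl <- table(factor(x$exams$truth, levels = TRUTH_LEVELS))
  cat("<reading_dataset>\n")
  cat(sprintf("  exams:    %d (%d normal, %d benign, %d cancer)\n",
              nrow(x$exams), cl[["normal"]], cl[["benign"]], cl[["cancer"]]))
  cat(sprintf("  readings: %d by %d reader(s) in %d block(s)\n",
              nrow(x$readings), length(unique(x$readings$reader_id)),
              length(unique(x$exams$study_id))))
  invisible(x)
}
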
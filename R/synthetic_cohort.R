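#' Default AI-category distributions by ground-truth class
#'
#' Ten-category probability vectors for normal, cancer and benign exams.
#' The calibrated score assigns roughly 10% of normal screening exams to
#' each category (mean 10.0% per category here, every category within the
#' observed 7.2--14.9% range, 17% of normals at or below category 2 and
#' 47% at or below category 5). Cancer exams concentrate at the top:
#' 72.5% in category 10 and 95.1% in categories 5--10, with 1% at or
#' below category 2 and 7% at or below category 5. Benign exams sit in
#' between: 27% in category 10, 5% at or below category 2 and 27% at or
#' below category 5. Within these constraints the remaining split is a
#' package default, documented in the methods vignette.
#'
#' @return Named list of three numeric vectors (`normal`, `cancer`,
#'   `benign`), each of length 10 summing to 1.
#' @export
default_distributions <- function() {
  d <- list(
    normal = c(8.0, 9.0, 10.0, 10.0, 10.0, 10.6, 10.6, 10.6, 10.6, 10.6),
    cancer = c(0.4, 0.6, 1.7, 2.2, 2.1, 3.0, 4.5, 5.5, 7.5, 72.5),
    benign = c(2.0, 3.0, 6.0, 8.0, 8.0, 10.0, 11.0, 12.0, 13.0, 27.0)
  )
  lapply(d, function(p) {
    p <- p / 100
    stopifnot(abs(sum(p) - 1) < 1e-9)
    p
  })
}

#' Largest-remainder apportionment of n items over a probability vector
#'
#' Deterministic rounding of `n * probs` to integers summing to `n`:
#' floors first, then one extra item per category in order of decreasing
#' fractional remainder (ties broken by lower category index).
#'
#' @param n total count (non-negative integer).
#' @param probs non-negative weights summing to 1.
#' @return Integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, probs) {
  if (n < 0) mt_abort("n must be non-negative", "mt_config_error")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    mt_abort("probs must be non-negative and sum to 1", "mt_config_error")
  target <- n * probs
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- target - base
    extra <- order(-frac, seq_along(probs))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Reader behaviour model for the synthetic cohort
#'
#' Radiologist scores are generated from a Gaussian latent-suspicion
#' model (binormal reader ROC). Each exam gets a latent suspicion
#' `mu_class + lambda_ai * (ai_category - 5.5)/4.5 + exam effect`, where
#' `mu_class` is `mu_pos` for cancer and `mu_neg` otherwise, the AI
#' coupling term is centred on the category midpoint, and the exam effect
#' is `N(0, sigma_exam^2)`. Each reading adds independent reader noise
#' `N(0, sigma_reader^2)` and is clipped to the score scale. A positive
#' `lambda_ai` makes low-AI-category cancers tend to receive low reader
#' scores as well (cancers missed by the AI system tend to be the ones
#' radiologists miss).
#'
#' Defaults place the reader-averaged AUC near 0.87, typical of breast
#' radiologists in enriched observer studies; see the methods vignette
#' for the calculation behind the default means and spreads.
#'
#' @param n_studies number of disjoint study blocks. The per-block case
#'   mix follows from the cohort class counts, apportioned as evenly as
#'   possible over blocks.
#' @param readers_per_study readers per block (each block has its own).
#' @param mu_pos,mu_neg latent mean suspicion of cancer / non-cancer exams.
#' @param sigma_exam between-exam latent spread (> 0).
#' @param sigma_reader within-reader noise (> 0).
#' @param lambda_ai coupling of latent suspicion to AI category (>= 0).
#' @param scale_min,scale_max emitted score scale (level-of-suspicion
#'   1--10 by default).
#' @return Object of class `reader_model`.
#' @export
reader_model <- function(n_studies = 9L,
                         readers_per_study = 11L,
                         mu_pos = 5.4, mu_neg = 4.0,
                         sigma_exam = 1.2, sigma_reader = 0.8,
                         lambda_ai = 1.5,
                         scale_min = 1, scale_max = 10) {
  if (sigma_exam <= 0 || sigma_reader <= 0)
    mt_abort("sigma_exam and sigma_reader must be > 0", "mt_config_error")
  if (mu_pos <= mu_neg)
    mt_abort("mu_pos must exceed mu_neg", "mt_config_error")
  if (lambda_ai < 0)
    mt_abort("lambda_ai must be >= 0", "mt_config_error")
  if (scale_min >= scale_max)
    mt_abort("scale_min must be < scale_max", "mt_config_error")
  structure(list(n_studies = as.integer(n_studies),
                 readers_per_study = as.integer(readers_per_study),
                 mu_pos = mu_pos, mu_neg = mu_neg,
                 sigma_exam = sigma_exam, sigma_reader = sigma_reader,
                 lambda_ai = lambda_ai,
                 scale_min = scale_min, scale_max = scale_max),
            class = "reader_model")
}

#' Cohort configuration
#'
#' Bundles class counts, per-class AI-category distributions, a reader
#' model and a seed. The default sizes reproduce the pooled-study
#' composition used throughout the package's examples: 1233 normal, 768
#' benign and 653 cancer exams in 9 study blocks with 11 readers each.
#'
#' @param n_normal,n_benign,n_cancer exam counts by ground-truth class.
#' @param distributions named list of three length-10 probability
#'   vectors; defaults to [default_distributions()].
#' @param model a [reader_model()].
#' @param exact_proportions if `TRUE`, AI-category counts per class are
#'   the largest-remainder apportionment of `n * probs` (deterministic);
#'   otherwise categories are drawn multinomially.
#' @param seed integer seed controlling all randomness.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_normal = 1233L, n_benign = 768L,
                          n_cancer = 653L,
                          distributions = default_distributions(),
                          model = reader_model(),
                          exact_proportions = FALSE,
                          seed = 20190416L) {
  counts <- c(n_normal, n_benign, n_cancer)
  if (any(counts < 0))
    mt_abort("class counts must be non-negative", "mt_config_error")
  stopifnot(all(c("normal", "cancer", "benign") %in% names(distributions)))
  structure(list(n_normal = as.integer(n_normal),
                 n_benign = as.integer(n_benign),
                 n_cancer = as.integer(n_cancer),
                 distributions = distributions,
                 model = model,
                 exact_proportions = isTRUE(exact_proportions),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Preset reproducing the pooled nine-study composition
#'
#' 2654 exams (1233 normal, 768 benign, 653 cancer) split as evenly as
#' possible over 9 blocks of 11 readers each.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
fixture_config <- function(seed = 20190416L, ...) {
  cohort_config(n_normal = 1233L, n_benign = 768L, n_cancer = 653L,
                seed = seed, ...)
}

# Block assignment: spread each class as evenly as possible over blocks,
# deterministically (largest remainder on uniform weights).
assign_blocks <- function(n, n_studies) {
  per <- largest_remainder(n, rep(1 / n_studies, n_studies))
  rep(seq_len(n_studies), times = per)
}

#' Generate an exam table
#'
#' Draws AI categories per ground-truth class from the configured
#' category distributions and assigns exams to study blocks. With
#' `exact_proportions = TRUE` the per-class category counts are exactly
#' the largest-remainder apportionment of `n * probs`; categories are
#' then laid out in ascending order before block assignment so the
#' result is fully deterministic.
#'
#' @param config a [cohort_config()]. The RNG state is taken from
#'   `config$seed` unless the caller has already seeded.
#' @param use_seed seed the RNG from `config$seed` (default `TRUE`); set
#'   to `FALSE` when calling from a surrounding seeded generator.
#' @return data.frame in the exam-table contract.
#' @export
generate_exams <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (use_seed) set.seed(config$seed)
  classes <- c(normal = config$n_normal, benign = config$n_benign,
               cancer = config$n_cancer)
  n_studies <- config$model$n_studies
  out <- lapply(names(classes), function(cl) {
    n <- classes[[cl]]
    if (n == 0) return(NULL)
    probs <- config$distributions[[cl]]
    cats <- if (config$exact_proportions) {
      rep(1:10, times = largest_remainder(n, probs))
    } else {
      sample(1:10, n, replace = TRUE, prob = probs)
    }
    data.frame(truth = cl, ai_category = as.integer(cats),
               study_id = assign_blocks(n, n_studies),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(exam_id = character(), study_id = character(),
                      truth = character(), ai_category = integer(),
                      raw_score = numeric(), stringsAsFactors = FALSE))
  data.frame(exam_id = sprintf("E%05d", seq_len(nrow(out))),
             study_id = paste0("S", out$study_id),
             truth = out$truth,
             ai_category = out$ai_category,
             raw_score = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate a reading table for an exam table
#'
#' Every reader of a block scores every exam of that block (fully
#' crossed within block). Draw order is fixed and documented so seeds
#' are portable: exam latent effects first (in exam-table row order),
#' then per-block reader-noise matrices (blocks in order, readers within
#' block in order, exams within reader in order).
#'
#' @param exams exam table as produced by [generate_exams()].
#' @param model a [reader_model()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return data.frame in the reading-table contract.
#' @export
generate_readings <- function(exams, model, seed = NULL) {
  stopifnot(inherits(model, "reader_model"))
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(exams$study_id)) || any(!nzchar(exams$study_id)))
    mt_abort("every exam needs a study assignment", "mt_generation_error")
  mu <- ifelse(exams$truth == "cancer", model$mu_pos, model$mu_neg)
  latent <- mu +
    model$lambda_ai * (exams$ai_category - 5.5) / 4.5 +
    rnorm(nrow(exams), 0, model$sigma_exam)
  blocks <- unique(exams$study_id)
  reader_counter <- 0L
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    idx <- which(exams$study_id == b)
    readers <- sprintf("R%03d", reader_counter + seq_len(model$readers_per_study))
    reader_counter <- reader_counter + model$readers_per_study
    noise <- matrix(rnorm(length(readers) * length(idx), 0,
                          model$sigma_reader),
                    nrow = length(readers), byrow = TRUE)
    score <- pmin(pmax(rep(latent[idx], each = length(readers)) +
                         as.vector(noise),
                       model$scale_min), model$scale_max)
    out[[bi]] <- data.frame(
      exam_id = rep(exams$exam_id[idx], each = length(readers)),
      reader_id = rep(readers, times = length(idx)),
      study_id = b,
      score = score,
      scale_min = model$scale_min,
      scale_max = model$scale_max,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a pooled split-plot reading dataset
#'
#' Produces `n_studies` disjoint blocks, each with its own readers and
#' exams and fully crossed within block, pooled into one validated
#' [reading_dataset()]. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A `reading_dataset`.
#' @export
generate_split_plot <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  exams <- generate_exams(config, use_seed = FALSE)
  readings <- generate_readings(exams, config$model, seed = NULL)
  reading_dataset(exams, readings)
}
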
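# Independent oracles and tiny fixture builders, kept deliberately
# brute-force so they share no code path with the implementation.

# Mann-Whitney success average by explicit double loop
brute_force_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# trapezoid integral by explicit summation
brute_force_trapezoid <- function(x, y) {
  a <- 0
  for (i in seq_len(length(x) - 1))
    a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  a
}

# a tiny valid exam table
tiny_exams <- function() {
  data.frame(
    exam_id = c("a", "b", "c", "d", "e", "f"),
    study_id = "S1",
    truth = c("cancer", "cancer", "benign", "normal", "normal", "normal"),
    ai_category = c(10L, 3L, 7L, 1L, 5L, 9L),
    raw_score = NA_real_,
    stringsAsFactors = FALSE)
}

# readings for tiny_exams: two readers, fully crossed, 1-10 scale
tiny_readings <- function(scores_r1 = c(9, 4, 6, 2, 3, 5),
                          scores_r2 = c(8, 2, 7, 1, 4, 6)) {
  ex <- tiny_exams()
  data.frame(
    exam_id = rep(ex$exam_id, 2),
    reader_id = rep(c("R1", "R2"), each = nrow(ex)),
    study_id = "S1",
    score = c(scores_r1, scores_r2),
    scale_min = 1, scale_max = 10,
    stringsAsFactors = FALSE)
}

tiny_dataset <- function(...) reading_dataset(tiny_exams(), tiny_readings(...))

# small seeded split-plot cohort for MRMC tests
small_cohort <- function(seed = 42, n_studies = 3, readers = 4,
                         n_normal = 90, n_benign = 30, n_cancer = 60, ...) {
  cohort_config(n_normal = n_normal, n_benign = n_benign,
                n_cancer = n_cancer,
                model = reader_model(n_studies = n_studies,
                                     readers_per_study = readers, ...),
                seed = seed)
}

# random step ROC curves for averaging tests
random_reader_curve <- function(n1, n0, levels = 6) {
  reader_curve(scores = sample(seq_len(levels), n1 + n0, replace = TRUE) +
                 c(rep(1, n1), rep(0, n0)) * stats::rbinom(n1 + n0, 2, 0.5),
               truth = c(rep(TRUE, n1), rep(FALSE, n0)))
}
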
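#' Trapezoidal (Mann-Whitney) AUC
#'
#' Nonparametric area under the empirical ROC curve. Computed via the
#' rank-sum identity: with `n1` positives and `n0` negatives,
#' `AUC = (R1 - n1(n1+1)/2) / (n1 n0)` where `R1` is the sum of
#' mid-ranks of the positive scores in the pooled sample. Ties count
#' one half, so this equals the mean over all (positive, negative)
#' pairs of the success kernel (1 if pos > neg, 1/2 if equal, 0
#' otherwise) and also the trapezoidal area of the empirical ROC curve.
#'
#' @param pos_scores,neg_scores numeric vectors, each non-empty.
#' @return AUC in `[0, 1]`.
#' @export
trapezoidal_auc <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores); n0 <- length(neg_scores)
  if (n1 == 0 || n0 == 0)
    mt_abort("AUC needs at least one positive and one negative score",
             "mt_estimation_error")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical (trapezoidal) ROC curve of one reader
#'
#' Sweeps the decision threshold over the reader's distinct scores and
#' returns the ROC vertices from (0,0) to (1,1). The trapezoidal area of
#' the returned polyline equals [trapezoidal_auc()] on the same scores.
#'
#' @param scores numeric reader scores.
#' @param truth logical (positive = `TRUE`) or character truth labels
#'   (converted with [binary_truth()]).
#' @param reader_id optional label stored on the result.
#' @return Object of class `reader_curve` with fields `reader_id`,
#'   `points` (data.frame `fpf`, `tpf`) and `auc`.
#' @export
reader_curve <- function(scores, truth, reader_id = NA_character_) {
  if (is.character(truth)) truth <- binary_truth(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    mt_abort("reader has scores for only one truth class",
             "mt_estimation_error")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpf <- c(0, vapply(thr, function(t) sum(scores[truth] >= t) / n1, 0))
  fpf <- c(0, vapply(thr, function(t) sum(scores[!truth] >= t) / n0, 0))
  if (fpf[length(fpf)] < 1 || tpf[length(tpf)] < 1) { # cannot happen, guard
    fpf <- c(fpf, 1); tpf <- c(tpf, 1)
  }
  pts <- data.frame(fpf = fpf, tpf = tpf)
  structure(list(reader_id = reader_id, points = pts,
                 auc = trapezoid_area(pts$fpf, pts$tpf)),
            class = "reader_curve")
}

# trapezoidal area under a polyline with non-decreasing x
trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area-preserving average of reader ROC curves
#'
#' Averages empirical reader curves along directions perpendicular to
#' the chance line: each curve is rotated 45 degrees (u = (fpf+tpf)/sqrt2,
#' v = (tpf-fpf)/sqrt2, so the chance diagonal becomes the horizontal
#' axis), linearly interpolated on a common grid of abscissae, averaged
#' pointwise, and rotated back. The common grid is the uniform
#' `grid_size`-point grid augmented with every input curve's own vertex
#' abscissae, which makes the interpolation exact for the piecewise
#' linear curves and hence the averaging area-preserving to machine
#' precision: the AUC of the averaged curve equals the arithmetic mean
#' of the input AUCs. Duplicate abscissae within a curve are resolved by
#' the upper envelope.
#'
#' @param curves list of [reader_curve()] objects (at least one).
#' @param grid_size number of uniform grid points (>= 2; default 1001).
#' @return Object of class `averaged_curve` with `points` and `auc`.
#' @export
average_curves <- function(curves, grid_size = 1001L) {
  if (length(curves) == 0)
    mt_abort("need at least one curve to average", "mt_argument_error")
  stopifnot(all(vapply(curves, inherits, TRUE, "reader_curve")),
            grid_size >= 2)
  s2 <- sqrt(2)
  rot <- lapply(curves, function(cv) {
    u <- (cv$points$fpf + cv$points$tpf) / s2
    v <- (cv$points$tpf - cv$points$fpf) / s2
    # u is non-decreasing along the curve; collapse duplicates to the
    # upper envelope so v is a function of u
    if (anyDuplicated(u)) {
      uu <- unique(u)
      v <- vapply(uu, function(x) max(v[u == x]), 0)
      u <- uu
    }
    list(u = u, v = v)
  })
  grid <- sort(unique(c(seq(0, s2, length.out = grid_size),
                        unlist(lapply(rot, `[[`, "u")))))
  vbar <- rowMeans(vapply(rot, function(r)
    stats::approx(r$u, r$v, xout = grid, rule = 2)$y,
    numeric(length(grid))))
  pts <- data.frame(fpf = (grid - vbar) / s2, tpf = (grid + vbar) / s2)
  structure(list(points = pts, auc = trapezoid_area(pts$fpf, pts$tpf)),
            class = "averaged_curve")
}

#' @export
print.reader_curve <- function(x, ...) {
  cat(sprintf("<reader_curve> reader %s: %d vertices, AUC %.4f\n",
              x$reader_id, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
print.averaged_curve <- function(x, ...) {
  cat(sprintf("<averaged_curve> %d vertices, AUC %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}
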
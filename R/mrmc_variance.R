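#' @section Reader-averaged AUC and its unbiased variance:
#'
#' The reader-averaged empirical AUC is written as a weighted sum of
#' success indicators `psi(reader, positive case, negative case)` over
#' the realized design (psi = 1 / 0.5 / 0 for a correctly ordered /
#' tied / incorrectly ordered case pair). Its variance is estimated by
#' the U-statistic moment decomposition: second-order moments
#' `E[psi psi']` depend only on which indices the two triplets share
#' (same/different reader x same/different positive x same/different
#' negative = 8 moment classes); each class moment is estimated
#' unbiasedly by the average of `psi psi'` over the realized index
#' pairs of that class, and the variance combines them with
#' coefficients equal to the summed products of the design weights in
#' each class. The same decomposition applied to differences of success
#' indicators between two scenarios read by identical readers on
#' identical cases yields the variance of the AUC difference directly.
#' @name mrmc_variance
#' @keywords internal
NULL

# Pair sums of sum_{pairs in class k} X X' for a family of same-sized
# matrices X_r (readers x cases of one block), for the 8 shared-index
# classes: 1 same r,i,j; 2 same r,i diff j; 3 same r,j diff i;
# 4 same r diff i,j; 5 diff r same i,j; 6 diff r same i diff j;
# 7 diff r diff i same j; 8 all different. Ordered pairs, including
# self-pairs in class 1.
pair_class_sums <- function(X) {
  P <- Reduce(`+`, X)
  s1 <- sum(vapply(X, function(m) sum(m * m), 0))
  a <- sum(vapply(X, function(m) sum(rowSums(m)^2), 0))
  b <- sum(vapply(X, function(m) sum(colSums(m)^2), 0))
  e <- sum(vapply(X, function(m) sum(m)^2, 0))
  f <- sum(P * P)
  g <- sum(rowSums(P)^2)
  h <- sum(colSums(P)^2)
  G <- sum(P)
  s <- numeric(8)
  s[1] <- s1
  s[2] <- a - s1
  s[3] <- b - s1
  s[4] <- e - a - b + s1
  s[5] <- f - s1
  s[6] <- g - a - f + s1
  s[7] <- h - b - f + s1
  s[8] <- G^2 - sum(s[1:7])
  s
}

# Decompose a reading table into analysis units: one unit per
# (reader, study block), carrying the psi success matrix over the
# block's positive x negative cases and the read-indicator matrix D.
# Blocks are taken from the exams' study_id; case sets of different
# blocks are disjoint by construction of the exam table.
build_units <- function(ds, readings) {
  ex <- ds$exams
  pos_of <- stats::setNames(binary_truth(ex$truth), ex$exam_id)
  block_of <- stats::setNames(ex$study_id, ex$exam_id)
  readings$block <- unname(block_of[readings$exam_id])
  units <- list()
  for (b in unique(readings$block)) {
    ex_b <- ex[ex$study_id == b, ]
    pos_ids <- ex_b$exam_id[binary_truth(ex_b$truth)]
    neg_ids <- ex_b$exam_id[!binary_truth(ex_b$truth)]
    rd_b <- readings[readings$block == b, ]
    for (r in unique(rd_b$reader_id)) {
      sc <- stats::setNames(rep(NA_real_, nrow(ex_b)), ex_b$exam_id)
      rr <- rd_b[rd_b$reader_id == r, ]
      sc[rr$exam_id] <- rr$score
      sp <- sc[pos_ids]; sn <- sc[neg_ids]
      D <- outer(!is.na(sp), !is.na(sn), `&`)
      psi <- outer(sp, sn, `>`) + 0.5 * outer(sp, sn, `==`)
      psi[!D] <- 0
      units[[length(units) + 1L]] <-
        list(reader = r, block = b, psi = psi, D = D + 0,
             n1 = sum(!is.na(sp)), n0 = sum(!is.na(sn)))
    }
  }
  units
}

# Core estimator on a list of units whose psi matrices hold an
# arbitrary success kernel (plain psi for an AUC, psi differences for a
# paired scenario contrast). Returns the weighted reader average of
# the kernel and its unbiased variance estimate.
ustat_estimate <- function(units) {
  valid <- vapply(units, function(u) u$n1 > 0 && u$n0 > 0, TRUE)
  if (sum(valid) < length(units))
    mt_warn(sprintf("%d reader-block unit(s) with a single truth class dropped",
                    sum(!valid)), "mt_dropped_readers")
  units <- units[valid]
  if (length(units) == 0)
    mt_abort("no reader has both positive and negative cases",
             "mt_estimation_error")
  U <- length(units)
  w <- vapply(units, function(u) 1 / (U * u$n1 * u$n0), 0)
  unit_auc <- vapply(units, function(u) sum(u$psi) / (u$n1 * u$n0), 0)
  est <- mean(unit_auc)

  blocks <- vapply(units, `[[`, "", "block")
  num <- cnt <- coef <- numeric(8)
  for (b in unique(blocks)) {
    in_b <- which(blocks == b)
    psi_l <- lapply(units[in_b], `[[`, "psi")
    d_l <- lapply(units[in_b], `[[`, "D")
    w_l <- Map(`*`, d_l, w[in_b])
    num <- num + pair_class_sums(psi_l)
    cnt <- cnt + pair_class_sums(d_l)
    coef <- coef + pair_class_sums(w_l)
  }
  # cross-block unit pairs: different cases by construction; same
  # reader id in two blocks -> class 4, otherwise class 8
  g_psi <- vapply(units, function(u) sum(u$psi), 0)
  g_d <- vapply(units, function(u) u$n1 * u$n0, 0)
  g_w <- w * g_d
  cross <- function(g) {
    per_block <- vapply(unique(blocks), function(b) sum(g[blocks == b]), 0)
    sum(per_block)^2 - sum(per_block^2)
  }
  same_reader_cross <- function(g) {
    rd <- vapply(units, `[[`, "", "reader")
    tot <- 0
    for (r in unique(rd[duplicated(rd)])) {
      gi <- g[rd == r]
      tot <- tot + sum(gi)^2 - sum(gi^2)
    }
    tot
  }
  for (fam in list(list(g = g_psi, tgt = "num"),
                   list(g = g_d, tgt = "cnt"),
                   list(g = g_w, tgt = "coef"))) {
    tot <- cross(fam$g)
    sr <- same_reader_cross(fam$g)
    v <- get(fam$tgt)
    v[4] <- v[4] + sr
    v[8] <- v[8] + tot - sr
    assign(fam$tgt, v)
  }

  M <- ifelse(cnt > 0, num / pmax(cnt, 1), NA_real_)
  # unbiased estimate of the squared mean: the all-indices-different
  # moment; with a single reader fall back to the same-reader
  # different-cases moment (case-conditional variance), then to the
  # plug-in square
  mu2 <- if (cnt[8] > 0) M[8] else if (cnt[4] > 0) M[4] else {
    mt_warn("design too small for an unbiased variance; using plug-in mean square",
            "mt_variance_fallback")
    est^2
  }
  var_raw <- sum(coef[cnt > 0] * M[cnt > 0]) - mu2
  truncated <- var_raw < 0
  if (truncated)
    mt_warn(sprintf("negative variance estimate (%.3g) truncated to 0",
                    var_raw), "mt_negative_variance")
  list(estimate = est, var = max(var_raw, 0), var_raw = var_raw,
       truncated = truncated, n_units = U, unit_estimates = unit_auc,
       moments = M, coefficients = coef)
}

#' Reader-averaged AUC with unbiased U-statistic variance
#'
#' Computes the simple average over reader-block units of the
#' trapezoidal AUC and its variance under the random-reader,
#' random-case model, for fully crossed or split-plot (or any other
#' realized) designs. Readers lacking one truth class are dropped with
#' a warning. A negative variance estimate (possible for unbiased
#' moment estimators) is truncated to zero with a warning.
#'
#' @param ds a `reading_dataset`.
#' @param readings reading table to analyze; defaults to `ds$readings`
#'   (use a reassigned table for a pre-selection scenario).
#' @return List with `auc`, `var`, `var_raw`, `truncated`, `n_units`,
#'   `reader_aucs`.
#' @export
mrmc_auc <- function(ds, readings = ds$readings) {
  stopifnot(inherits(ds, "reading_dataset"))
  if (nrow(readings) == 0)
    mt_abort("no readings to analyze", "mt_estimation_error")
  res <- ustat_estimate(build_units(ds, readings))
  list(auc = res$estimate, var = res$var, var_raw = res$var_raw,
       truncated = res$truncated, n_units = res$n_units,
       reader_aucs = res$unit_estimates)
}

#' Paired AUC difference between two scenarios and its variance
#'
#' Applies the U-statistic moment decomposition to the differences of
#' success indicators between two reading tables defined on identical
#' readers and cases (e.g., a pre-selection scenario versus the
#' original reading), yielding the reader-averaged AUC difference and
#' the variance of that difference directly (correlations between the
#' paired scenarios are handled exactly, not via a correlation
#' approximation).
#'
#' @param ds a `reading_dataset`.
#' @param readings_scenario scenario reading table (same design as
#'   `readings_baseline`).
#' @param readings_baseline baseline reading table; defaults to
#'   `ds$readings`.
#' @return List with `delta` (scenario minus baseline), `var_delta`,
#'   `auc_baseline`, `auc_scenario`, `var_raw`, `truncated`, `n_units`.
#' @export
mrmc_delta <- function(ds, readings_scenario, readings_baseline = ds$readings) {
  stopifnot(inherits(ds, "reading_dataset"))
  u_base <- build_units(ds, readings_baseline)
  u_scen <- build_units(ds, readings_scenario)
  key <- function(u) paste(u$block, u$reader)
  if (!identical(vapply(u_base, key, ""), vapply(u_scen, key, "")) ||
      !identical(lapply(u_base, `[[`, "D"), lapply(u_scen, `[[`, "D")))
    mt_abort("scenario and baseline must share readers and case design",
             "mt_argument_error")
  u_diff <- Map(function(b, s) {
    b$psi <- s$psi - b$psi
    b
  }, u_base, u_scen)
  res <- ustat_estimate(u_diff)
  base <- ustat_estimate(u_base)
  scen <- ustat_estimate(u_scen)
  list(delta = res$estimate, var_delta = res$var,
       auc_baseline = base$estimate, auc_scenario = scen$estimate,
       var_baseline = base$var, var_scenario = scen$var,
       var_raw = res$var_raw, truncated = res$truncated,
       n_units = res$n_units)
}
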
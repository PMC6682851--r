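---
title: "Methods: AI triage simulation and split-plot MRMC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AI triage simulation and split-plot MRMC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package models

Population-based mammography screening reads enormous numbers of exams,
the vast majority normal. An AI system that scores each exam with a
calibrated integer category 1–10 (each category holding ~10% of normal
screening exams) suggests a triage strategy: exams at or below a
threshold are auto-reported normal and never shown to a radiologist.
Two questions follow. How much reading workload disappears, and how
many cancers go with it, as a function of the threshold? And if the
radiologists read only the pre-selected remainder, does their
collective detection performance (reader-averaged AUC) stay within an
acceptable margin of the original?

The package answers both on simulated (or user-supplied) multi-reader
multi-case data. The pre-selection scenario is imposed *a posteriori*:
every radiologist score of an excluded exam is reassigned to the lowest
value of its scale, and scores of pre-selected exams are left
bit-identical — an explicit invariance-of-reader-behaviour assumption.
Whether that assumption holds in live screening (prevalence effects,
reading order, deliberate recall-threshold changes) is out of scope
here.

## Triage engine

**Calibration.** `calibrate()` maps a continuous AI output to the ten
categories using the k/10 empirical quantiles of the *normal* exams
only, so categories are deciles of the normal score distribution and
are independent of how enriched the analyzed sample is. We use type-1
(inverse empirical CDF) quantiles with the order-statistic index
`ceiling(n*k/10)` computed in exact integer arithmetic; R's
`quantile(type = 1)` can misplace the index by one through the
floating-point representation of the probability (0.3 × 20 is not 6 in
doubles). Interval assignment is right-closed, `(cut[k-1], cut[k]] -> k`,
so ties at a cutpoint fall in the lower category and per-category
counts never exceed `ceiling(n/10)`.

**Partition semantics.** Excluded means `ai_category <= threshold`;
pre-selected means strictly greater. Two workload figures are reported
because the analyzed sample is cancer-enriched while a screening load
is ~99% normal: `workload_reduction_screening` is the excluded fraction
of normal exams (the operative screening quantity) and
`workload_reduction_sample` is the excluded fraction of the whole
sample. Benign and normal exams are reported separately by the sweep,
but both are ROC negatives: the AUC measures cancer detection.

## Synthetic cohort: the stated world

The generator emulates the structure the analysis needs and nothing
more:

* **AI categories** per truth class are drawn from fixed ten-point
  distributions. The defaults are pinned to the published marginals:
  normals average 10.0% per category, every category inside
  [7.2%, 14.9%], with 17% at or below category 2 and 47% at or below
  category 5; cancers have 72.5% in category 10, 95.1% in categories
  5–10, 1% at or below 2 and 7% at or below 5; benigns have 27% in
  category 10, 5% at or below 2 and 27% at or below 5. Within those
  constraints the split is a free design choice, made once:

  | class  | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 | 9 | 10 |
  |--------|---|---|---|---|---|---|---|---|---|----|
  | normal | 8.0 | 9.0 | 10.0 | 10.0 | 10.0 | 10.6 | 10.6 | 10.6 | 10.6 | 10.6 |
  | cancer | 0.4 | 0.6 | 1.7 | 2.2 | 2.1 | 3.0 | 4.5 | 5.5 | 7.5 | 72.5 |
  | benign | 2 | 3 | 6 | 8 | 8 | 10 | 11 | 12 | 13 | 27 |

  With `exact_proportions = TRUE`, category counts are the
  largest-remainder rounding of `n * probs` (floors, then one extra per
  category by decreasing fractional remainder, ties to the lower
  category) — fully deterministic, used by the acceptance report.

* **Reader scores** follow a Gaussian latent-suspicion (binormal)
  model. Exam latent suspicion is
  `mu_class + lambda_ai * (ai_category - 5.5)/4.5 + N(0, sigma_exam^2)`
  with `mu_class = mu_pos` for cancers and `mu_neg` otherwise; each
  reading adds `N(0, sigma_reader^2)` noise and is clipped to a 1–10
  level-of-suspicion scale. `lambda_ai > 0` couples reader suspicion to
  the AI category, which is the load-bearing structural assumption:
  cancers the AI scores low are mostly cancers radiologists also score
  low, so excluding them costs little AUC. With `lambda_ai = 0` triage
  would delete detectable cancers at random and degrade AUC much
  faster.

* **Defaults** `mu_pos = 5.4`, `mu_neg = 4.0`, `sigma_exam = 1.2`,
  `sigma_reader = 0.8`, `lambda_ai = 1.5` were chosen (before any
  acceptance run, by the binormal formula) to put the reader-averaged
  AUC near 0.87, typical of breast radiologists in enriched observer
  studies: the AI coupling shifts the mean cancer latent by
  `1.5 * (9.12 - 5.5)/4.5 ≈ 1.21` (9.12 is the mean cancer category)
  and adds class-specific spread, giving
  `AUC ≈ Φ(Δ_eff / sqrt(σ_pos² + σ_neg²)) ≈ Φ(2.54/2.32) ≈ 0.86`.

* **Design.** Nine disjoint blocks, each with its own 11 readers and
  its own cases (class counts apportioned evenly over blocks), fully
  crossed within block — a split-plot design of 2654 exams
  (1233 normal / 768 benign / 653 cancer) and ~29k interpretations in
  the fixture preset. The original pooled studies' per-block reader
  counts are unpublished, so the printed totals (101 readers, 28,296
  interpretations) are approximated, not matched.

What the generator does **not** emulate: images, lesion histology,
breast density, vendor effects, interval-cancer dynamics, per-reader
skill differences (reader noise is exchangeable, so reader variance
arises from finite reading noise rather than persistent ability), and
BI-RADS's non-linear category usage. A green test therefore establishes
that the *pipeline arithmetic and estimators* behave as specified under
the stated world — not that a particular clinical deployment is safe.

## MRMC inference

**Reader-averaged AUC.** Each (reader, block) unit contributes its
trapezoidal AUC; units are weighted equally (a simple average over all
readers, blocks thereby weighted by reader count). Readers with a
single truth class are dropped with a warning for a stand-alone AUC;
under triage reassignment exams never disappear, so reader sets are
identical across scenarios and the paired contrast is well defined.

**Curve averaging.** Reader curves are rotated 45° so the chance line
is horizontal (`u = (FPF+TPF)/√2`, `v = (TPF−FPF)/√2`; along an
empirical ROC path `u` is strictly increasing, so `v(u)` is a
function; duplicate abscissae, if ever present, collapse to the upper
envelope). Curves are interpolated on a common grid, averaged
pointwise, and rotated back. The grid is the uniform `grid_size`-point
grid (default 1001) *augmented with every input curve's own vertex
abscissae*, which makes the linear interpolation exact for the
piecewise-linear inputs — area preservation then holds to machine
precision rather than to an O(grid⁻²) interpolation error.

**Variance.** Write the reader-averaged AUC as
`Â = Σ w(r,i,j) ψ(r,i,j)` over the realized design, with
`w = 1/(U n1_r n0_r)`. Since readers are exchangeable and cases i.i.d.
within class, `E[ψψ′]` depends only on which of the three indices the
two triplets share: 8 moment classes. Each class moment is estimated
unbiasedly by the average of `ψψ′` over the realized index pairs of the
class (computed in closed form from row/column/total sums, no explicit
pair enumeration), and
`Var(Â) = Σ_k C_k M_k − μ²` with `C_k` the summed weight products per
class and `μ²` estimated by the all-indices-different moment. The same
decomposition applied to ψ *differences* between two scenarios on the
identical design yields the variance of the paired AUC difference
directly, with the inter-scenario correlation handled exactly. Block
structure enters only through the realized pairs: cross-block pairs
share no cases, and a reader id appearing in several blocks is treated
as the same reader (those pairs land in the same-reader,
different-cases class).

Numerical choices and edge cases:

* Unbiased moment estimators can produce a negative variance; it is
  truncated to zero with a classed warning, keeping the raw value
  available (`var_raw`).
* With a single reader there are no all-different-reader pairs; `μ²`
  falls back to the same-reader different-cases moment (the
  case-conditional variance), and for degenerate designs with no such
  pairs either, to the plug-in square with a warning.
* CIs use the normal approximation, not t: degrees-of-freedom recipes
  differ across the MRMC literature and none is canonical for pooled
  split-plot designs.
* Non-inferiority is declared when the Bonferroni-corrected lower CI
  bound of Δ exceeds −margin (default 0.05). A stricter variant that
  additionally requires Δ > 0 appears in parts of the literature; it is
  available via `require_positive_delta = TRUE` but off by default,
  since the CI-bound form is the one the decision rule in practice
  reduces to.
* The Bonferroni divisor defaults to the number of thresholds actually
  evaluated (9 for a full sweep).

**Estimator validation.** The test suite checks the variance estimator
three ways: symbolic reductions (duplicate readers add no reader
variance; all-ψ-equal designs give zero), an exhaustive
pair-enumeration oracle on tiny designs, and a Monte-Carlo
unbiasedness check on crossed and split-plot designs (estimator mean
vs empirical variance of the AUC over replicates, 10% tolerance). One
caveat worth knowing: the generator draws a *stratified* case mix
(fixed class counts), while the estimator models cases as i.i.d.;
this makes the true replicate-to-replicate variance slightly smaller
than the estimand, and the observed mean-estimate/empirical-variance
ratio sits a few percent above 1 — inside the stated tolerance, and in
the conservative direction for inference.

## Known limitations

* The reported AUC effects inherit the invariance-of-reader-behaviour
  assumption; prevalence-driven changes in reader operating points are
  not modeled.
* Exclusion percentages for cancers come from a cancer-enriched sample
  mixing screening and clinical cases; in a pure screening stream the
  excluded-cancer fraction would likely be lower.
* Per-histology, per-density and per-study stratified analyses are out
  of scope, as is any image processing: the AI category is an input,
  not a computed quantity.
* ROC curve fitting (binormal, proper ROC) and bootstrap/jackknife CIs
  are intentionally absent; the analysis is fully nonparametric.
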
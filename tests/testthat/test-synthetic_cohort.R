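test_that("default distributions satisfy every printed constraint", {
  d <- default_distributions()
  for (p in d) {
    expect_length(p, 10)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_equal(d$cancer[10], 0.725)
  expect_equal(sum(d$cancer[5:10]), 0.951)
  expect_equal(mean(d$normal), 0.100)
  expect_true(all(d$normal >= 0.072 & d$normal <= 0.149))
  expect_equal(d$benign[10], 0.27)
})

test_that("largest-remainder apportionment is exact and deterministic", {
  d <- default_distributions()
  expect_identical(largest_remainder(1000, d$normal),
                   c(80L, 90L, 100L, 100L, 100L, 106L, 106L, 106L, 106L, 106L))
  # property: sums to n and within 1 of n*p, over random weight vectors
  set.seed(99)
  for (i in 1:50) {
    p <- runif(10); p <- p / sum(p)
    n <- sample(0:500, 1)
    cnt <- largest_remainder(n, p)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - n * p) < 1))
  }
  expect_error(largest_remainder(-1, d$normal), class = "mt_config_error")
})

test_that("generate_exams honours exact proportions and class counts", {
  cfg <- cohort_config(n_normal = 1000, n_benign = 0, n_cancer = 0,
                       exact_proportions = TRUE, seed = 1)
  ex <- generate_exams(cfg)
  expect_identical(as.vector(table(factor(ex$ai_category, levels = 1:10))),
                   c(80L, 90L, 100L, 100L, 100L, 106L, 106L, 106L, 106L, 106L))

  empty <- generate_exams(cohort_config(0, 0, 0, seed = 1))
  expect_equal(nrow(empty), 0)

  fx <- generate_exams(fixture_config(seed = 3))
  expect_equal(nrow(fx), 2654)
  expect_equal(as.vector(table(factor(fx$truth,
                                      c("normal", "benign", "cancer")))),
               c(1233L, 768L, 653L))
})

test_that("sampled category frequencies converge to the configured law", {
  cfg <- cohort_config(n_normal = 50000, n_benign = 0, n_cancer = 0,
                       seed = 2024)
  ex <- generate_exams(cfg)
  obs <- table(factor(ex$ai_category, levels = 1:10))
  gof <- suppressWarnings(
    chisq.test(obs, p = default_distributions()$normal))
  expect_gt(gof$p.value, 0.01)
})

test_that("reading generation is reproducible and degenerate limits hold", {
  cfg <- small_cohort(seed = 5)
  ds1 <- generate_split_plot(cfg)
  ds2 <- generate_split_plot(cfg)
  expect_identical(ds1$readings, ds2$readings)

  # 3 blocks x 4 readers x 60 exams, fully crossed within block
  expect_equal(nrow(ds1$readings), 3 * 4 * 60)
  expect_true(all(design_summary(ds1)$fully_crossed))

  # near-perfect separation limit: wide class gap, tiny noise, no coupling
  sep <- cohort_config(n_normal = 30, n_benign = 10, n_cancer = 20,
                       model = reader_model(n_studies = 1,
                                            readers_per_study = 3,
                                            mu_pos = 900, mu_neg = 100,
                                            sigma_exam = 1e-3,
                                            sigma_reader = 1e-3,
                                            lambda_ai = 0,
                                            scale_min = 0, scale_max = 1000),
                       seed = 8)
  a <- mrmc_auc(generate_split_plot(sep))
  expect_equal(a$auc, 1.0)

  # null model: no class separation forbidden by constructor, so check
  # a minimal gap drowned in noise gives AUC near 1/2
  null <- cohort_config(n_normal = 400, n_benign = 0, n_cancer = 400,
                        model = reader_model(n_studies = 1,
                                             readers_per_study = 4,
                                             mu_pos = 5.001, mu_neg = 5,
                                             sigma_exam = 1, sigma_reader = 1,
                                             lambda_ai = 0),
                        seed = 9)
  a0 <- mrmc_auc(generate_split_plot(null))
  expect_lt(abs(a0$auc - 0.5), 0.05)
})

test_that("reader AUC is monotone in class separation", {
  gaps <- c(0.3, 0.8, 1.6, 3.0)
  aucs <- vapply(gaps, function(g) {
    cfg <- cohort_config(n_normal = 150, n_benign = 50, n_cancer = 100,
                         model = reader_model(n_studies = 1,
                                              readers_per_study = 5,
                                              mu_pos = 4 + g, mu_neg = 4,
                                              lambda_ai = 0),
                         seed = 314)
    mrmc_auc(generate_split_plot(cfg))$auc
  }, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("invalid model parameters are rejected", {
  expect_error(reader_model(sigma_exam = 0), class = "mt_config_error")
  expect_error(reader_model(mu_pos = 1, mu_neg = 2),
               class = "mt_config_error")
  expect_error(reader_model(lambda_ai = -1), class = "mt_config_error")
  expect_error(cohort_config(n_normal = -5), class = "mt_config_error")
})
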
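test_that("the classification statistic is the symmetric idempotent minimum", {
  expect_equal(asi_class(4.2, 3.1), 3.1)
  expect_equal(asi_class(3.1, 4.2), 3.1)
  expect_equal(asi_class(2.7, 2.7), 2.7)
  expect_equal(asi_class(c(1, 5), c(2, 4)), c(1, 4))
  expect_error(asi_class(NA, 3), class = "asindex_incomplete_subject_error")
})

test_that("threshold classification computes confusion-matrix metrics", {
  scores <- c(5.1, 4.8, 2.2, 1.9)
  labels <- c("normal", "normal", "abnormal", "abnormal")
  res <- classify_asi(scores, labels, threshold = 3.6)
  expect_equal(res$accuracy, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)

  # a threshold of zero leaves every (positive) score classified normal
  res0 <- classify_asi(scores, labels, threshold = 0)
  expect_true(all(res0$predictions == "normal"))
  expect_equal(res0$sensitivity, 0)

  # threshold monotonicity: sensitivity never decreases as the cut rises
  set.seed(2)
  sc <- runif(40, 0, 8)
  lb <- sample(c("normal", "abnormal"), 40, TRUE)
  sens <- vapply(seq(0, 9, by = 0.5), function(th)
    classify_asi(sc, lb, th)$sensitivity, numeric(1))
  expect_true(all(diff(sens) >= 0))

  one_class <- classify_asi(c(1, 2), c("abnormal", "abnormal"), 3.6)
  expect_true(is.na(one_class$specificity))
  expect_equal(one_class$sensitivity, 1)
})

test_that("31 subjects with one miss print as 96.77% accuracy", {
  scores <- c(seq(4, 6, length.out = 13), 3.0,      # one normal below cut
              seq(1, 3.4, length.out = 17))
  labels <- rep(c("normal", "abnormal"), c(14, 17))
  res <- classify_asi(scores, labels, threshold = 3.6)
  expect_equal(res$n_misclassified, 1)
  expect_equal(res$accuracy, 30 / 31)
  expect_identical(sprintf("%.2f", 100 * res$accuracy), "96.77")
})

test_that("trapezoid AUC equals brute-force pair counting, including ties", {
  expect_equal(asi_roc(c(1, 2, 6, 7), c("abnormal", "abnormal", "normal",
                                        "normal"))$auc, 1)
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    scores <- sample(1:8, n, replace = TRUE) +
      sample(c(0, 0.5), n, replace = TRUE)      # heavy ties
    labels <- sample(c("normal", "abnormal"), n, TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("normal", "abnormal")
    expect_equal(asi_roc(scores, labels)$auc, auc_pair_count(scores, labels))
  }

  # labels independent of scores: AUC near 1/2
  set.seed(8)
  sc <- rnorm(4000); lb <- sample(c("normal", "abnormal"), 4000, TRUE)
  expect_lt(abs(asi_roc(sc, lb)$auc - 0.5), 0.05)

  expect_error(asi_roc(1:3, rep("normal", 3)),
               class = "asindex_statistics_error")
})

test_that("ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- round(rnorm(60, 5), 1)
  labels <- ifelse(scores + rnorm(60) < 5, "abnormal", "normal")
  if (length(unique(labels)) < 2) labels[1:2] <- c("normal", "abnormal")
  ours <- asi_roc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("normal", "abnormal"), direction = ">",
                   quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
})

test_that("Youden threshold maximizes sensitivity + specificity - 1", {
  scores <- c(1, 2, 3, 4.5, 5, 6)
  labels <- c("abnormal", "abnormal", "abnormal", "normal", "normal", "normal")
  y <- youden_threshold(asi_roc(scores, labels))
  expect_equal(y$youden_j, 1)
  expect_gte(y$threshold, 3)
  expect_lt(y$threshold, 4.5)
})

test_that("group difference test is a two-sided Welch t", {
  g <- c(1.1, 2.3, 3.2, 0.4)
  res <- group_difference_test(g, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(21)
  a <- rnorm(14, 5, 0.1); b <- rnorm(17, 2, 0.1)
  res2 <- group_difference_test(a, b)
  expect_lt(res2$p_value, 1e-10)
  ref <- t.test(a, b)                       # closed-form cross-check
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(group_difference_test(b, a)$statistic, -res2$statistic)

  const <- group_difference_test(c(1, 1), c(1, 1))
  expect_equal(const$p_value, 1)
  expect_error(group_difference_test(1, c(1, 2)),
               class = "asindex_statistics_error")
})

test_that("age regression recovers planted trends and degenerates gracefully", {
  pma <- seq(36, 42, length.out = 24)
  flat <- pma_regression(rep(4, 24) + rep(c(0, 1e-9), 12), pma)
  expect_lt(abs(flat$slope[1]), 1e-9)

  set.seed(31)
  scores <- 2 + 0.5 * pma + rnorm(24, 0, 0.3)
  fit <- pma_regression(scores, pma)
  se <- (fit$ci_hi[1] - fit$ci_lo[1]) / (2 * qt(0.975, 22))
  expect_lt(abs(fit$slope[1] - 0.5), 2 * se)

  grp <- rep(c("normal", "abnormal"), 12)
  both <- pma_regression(scores, pma, grp)
  expect_equal(both$fit, c("pooled", "normal", "abnormal"))

  expect_error(pma_regression(1:5, rep(40, 5)), class = "asindex_argument_error")
  expect_error(pma_regression(1:2, c(36, 40)), class = "asindex_statistics_error")
})

test_that("data-budget regimes skip impossible splits and collapse rules for single epochs", {
  m <- test_model()
  co <- generate_cohort(cohort_spec(2, 2, model = m, seed = 3))
  pair <- default_pairs()[["C3O1-C4O2"]]
  summ <- analyze_cohort(co, pair,
                         default_schemes()[c("2.5min_x4", "5min_x2", "10min_x1")])
  expect_warning(res <- data_budget_study(summ), "skipped")
  expect_false(any(res$budget_min == 5 & res$window_min == 10))
  expect_true(all(res$auc >= 0 & res$auc <= 1))

  # with a single epoch in play the combine rule is irrelevant
  b5 <- res[res$budget_min == 5 & res$window_min == 2.5, ]
  expect_equal(length(unique(b5$auc)), 1L)

  # 20-min mean/min/max differ only when the two epoch means differ
  rows <- summ[summ$scheme_id == "2.5min_x4", ]
  m1 <- vapply(rows$pw1, mean, numeric(1))
  m2 <- vapply(rows$pw2, mean, numeric(1))
  b20 <- res[res$budget_min == 20 & res$window_min == 2.5, ]
  if (all(m1 == m2)) expect_equal(length(unique(b20$auc)), 1L)
})
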
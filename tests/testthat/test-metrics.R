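test_that("confusion metrics agree with exact fractions", {
  m <- confusion_metrics(TP = 24, FN = 6, TN = 29, FP = 1)
  expect_equal(m$accuracy, 100 * 53 / 60)
  expect_equal(m$sensitivity, 100 * 24 / 30)
  expect_equal(m$specificity, 100 * 29 / 30)

  m2 <- confusion_metrics(TP = 18, FN = 12, TN = 30, FP = 0)
  expect_equal(round(unlist(m2), 2),
               c(accuracy = 80, sensitivity = 60, specificity = 100))

  perfect <- confusion_metrics(TP = 5, FN = 0, TN = 5, FP = 0)
  expect_equal(unlist(perfect),
               c(accuracy = 100, sensitivity = 100, specificity = 100))

  # accepts a named vector too; undefined metrics are NA
  expect_equal(confusion_metrics(c(TP = 1, FN = 1, TN = 1, FP = 1))$accuracy, 50)
  expect_true(is.na(confusion_metrics(TP = 0, FN = 0, TN = 3, FP = 1)$sensitivity))
  expect_error(confusion_metrics(TP = 0, FN = 0, TN = 0, FP = 0), "empty")
})

test_that("roc_auc equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), positive = 1),
               0.75)
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.0)

  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    labels <- c("high", "low", sample(c("high", "low"), n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.25), n, TRUE)  # coarse grid forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c("high", "high", "high")), "both classes")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- rnorm(200)
  labels <- ifelse(rnorm(200) + scores > 0, "high", "low")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("low", "high"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("label-score independence gives AUC near one half", {
  set.seed(5)
  auc <- roc_auc(runif(1000), sample(c("high", "low"), 1000, TRUE))
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("group_compare flags follow the p-value thresholds", {
  set.seed(13)
  same <- rnorm(50)
  expect_equal(group_compare(same, same)$flag, "")

  a <- rnorm(200)
  b <- rnorm(200, mean = 2)
  expect_equal(group_compare(a, b)$flag, "*")

  # frozen borderline pair: Welch p = 0.094, in (0.05, 0.1)
  ga <- c(0, 1, 2, 3, 4)
  gb <- ga + 1.9
  res <- group_compare(ga, gb, index = "CV1")
  expect_gt(res$p_value, 0.05)
  expect_lt(res$p_value, 0.1)
  expect_equal(res$flag, "+")
  expect_equal(res$index, "CV1")

  # affine rescaling of both groups leaves the p-value unchanged
  res2 <- group_compare(10 + 3 * ga, 10 + 3 * gb)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)

  # zero variance in both groups with equal means
  expect_equal(group_compare(rep(1, 3), rep(1, 4))$p_value, 1)
  expect_error(group_compare(1, 1:5), "at least 2")
})

test_that("recording_duration performs the pulse-count arithmetic", {
  expect_equal(recording_duration(30, 72), 25)
  expect_equal(recording_duration(72, 72), 60)
  expect_equal(recording_duration(0, 60), 0)
  expect_error(recording_duration(30, 0), "positive")
  expect_error(recording_duration(-1, 60), "non-negative")
})
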
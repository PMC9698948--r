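test_that("all eight methods separate two well-separated blobs", {
  ft <- blob_features(n_per_class = 90, sep = 4)
  ev <- train_eval_threefold(ft, methods = "all", seed = 1, select = FALSE)
  avg <- ev$metrics[ev$metrics$fold == "Average", ]
  expect_setequal(avg$method, c("SVM", "MLP", "GNB", "DT", "RF", "LR", "LDA", "KNN"))
  expect_true(all(avg$accuracy > 95))
  expect_true(all(avg$auc > 0.95))
})

test_that("threefold results mirror the fold/average table layout", {
  ev <- train_eval_threefold(blob_features(60), methods = c("RF", "KNN"),
                             seed = 2, select = FALSE)
  expect_s3_class(ev, "pulse_eval")
  expect_equal(ev$protocol, "threefold")
  for (m in c("RF", "KNN"))
    expect_equal(ev$metrics$fold[ev$metrics$method == m],
                 c("1", "2", "3", "Average"))
  expect_true(all(ev$metrics$accuracy >= 0 & ev$metrics$accuracy <= 100))
  expect_true(all(ev$metrics$auc >= 0 & ev$metrics$auc <= 1))
  # confusion counts cover each fold completely
  f1 <- ev$metrics[ev$metrics$method == "RF" & ev$metrics$fold != "Average", ]
  expect_equal(sum(f1$TP + f1$FN + f1$TN + f1$FP), 120)
  expect_output(print(ev), "Threefold")
})

test_that("permuted labels drive the cross-validated AUC to one half", {
  # featureless inputs: the permutation null is centred at 0.5 with
  # Monte-Carlo error ~ 1/sqrt(20 folds x permutations)
  ft <- blob_features(n_per_class = 60, sep = 0)
  set.seed(31)
  aucs <- replicate(20, {
    ft$label <- sample(ft$label)
    ft$regime <- ifelse(ft$label == "high", "appropriate", "higher")
    ev <- train_eval_threefold(ft, methods = "RF", seed = 1, select = FALSE)
    ev$metrics$auc[ev$metrics$fold == "Average"]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("LOSO is perfect on separable data and never sees the held-out subject", {
  ft <- blob_features(n_per_class = 80, sep = 4, n_subjects = 8)
  ev <- leave_one_subject_out(ft, methods = "RF", seed = 3, select = FALSE)
  expect_equal(ev$protocol, "loso")
  expect_equal(ev$unit, "recording")
  row <- ev$metrics[ev$metrics$method == "RF", ]
  expect_equal(row$FP + row$FN, 0)
  expect_equal(row$accuracy, 100)
  expect_equal(row$auc, 1.0)
  # confusion counts sum to the number of evaluated recordings
  expect_equal(row$TP + row$FN + row$TN + row$FP, ev$n_units)

  # duplicated held-out rows are excluded by subject-id bookkeeping
  dup <- rbind(ft, ft[ft$subject == "s01", ])
  ev2 <- leave_one_subject_out(dup, methods = "LDA", seed = 3, select = FALSE)
  expect_s3_class(ev2, "pulse_eval")

  # beat-level counting unit
  evb <- leave_one_subject_out(ft, methods = "LDA", seed = 3,
                               unit = "beat", select = FALSE)
  rb <- evb$metrics
  expect_equal(rb$TP + rb$FN + rb$TN + rb$FP, nrow(ft))
})

test_that("a two-subject cohort runs LOSO with a stability warning", {
  ft <- blob_features(n_per_class = 40, n_subjects = 2)
  expect_warning(ev <- leave_one_subject_out(ft, methods = "LDA", seed = 1,
                                             select = FALSE),
                 "unstable")
  expect_s3_class(ev, "pulse_eval")
})

test_that("holdout splits by subject and reports CV plus a hold-out row", {
  ft <- blob_features(n_per_class = 100, n_subjects = 10)
  ev <- holdout_eval(ft, methods = c("RF", "LDA"), seed = 4, select = FALSE)
  expect_equal(ev$protocol, "holdout")
  for (m in c("RF", "LDA"))
    expect_equal(ev$metrics$fold[ev$metrics$method == m],
                 c("1", "2", "3", "Average", "Holdout"))
  expect_length(ev$train_subjects, 8)
  hold <- ev$metrics[ev$metrics$fold == "Holdout" & ev$metrics$method == "RF", ]
  expect_gt(hold$accuracy, 95)

  # identical seed reproduces the split and every metric
  ev2 <- holdout_eval(ft, methods = c("RF", "LDA"), seed = 4, select = FALSE)
  expect_identical(ev$metrics, ev2$metrics)
  expect_identical(ev$train_subjects, ev2$train_subjects)

  expect_error(holdout_eval(ft, seed = 1, split = 1.2), "split")
})

test_that("quality_eval dispatches on protocol and selection filters pools", {
  ft <- test_features()
  sel <- select_quality_beats(ft)
  expect_true(all(sel$label[sel$regime == "appropriate"] == "high"))
  expect_true(all(sel$label[sel$regime == "higher"] == "low"))
  expect_lt(nrow(sel), nrow(ft))

  ev <- quality_eval(ft, protocol = "threefold", methods = "LDA", seed = 5)
  expect_equal(ev$protocol, "threefold")
  expect_error(quality_eval(ft, protocol = "loso", methods = "nope"),
               "unknown method")
})
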
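#' @name classifiers
#' @title The eight quality classifiers
#' @description
#' Binary quality discrimination ("high" vs "low" quality pulses, with
#' "high" as the positive class) supports eight supervised methods:
#' support vector machine (`SVM`, RBF kernel, cost 1), multilayer
#' perceptron (`MLP`, one hidden layer of 32 units, at most 500
#' iterations), Gaussian naive Bayes (`GNB`), decision tree (`DT`, grown
#' without depth limit), random forest (`RF`, 100 trees), logistic
#' regression (`LR`), linear discriminant analysis (`LDA`) and K-nearest
#' neighbours (`KNN`, k = 5). Features are standardized with
#' training-portion statistics only; no test information leaks into
#' fitting. Hyperparameters are fixed, documented defaults overridable via
#' the `hyperparams` argument of the evaluation functions.
#' @keywords internal
NULL

clf_method_names <- function() c("SVM", "MLP", "GNB", "DT", "RF", "LR", "LDA", "KNN")

default_hyperparams <- function(overrides = list()) {
  hp <- list(svm_cost = 1, mlp_size = 32, mlp_maxit = 500, mlp_decay = 1e-4,
             knn_k = 5, rf_trees = 100, dt_cp = 0, dt_minsplit = 2)
  hp[names(overrides)] <- overrides
  hp
}

resolve_methods <- function(methods) {
  all <- clf_method_names()
  if (identical(methods, "all")) return(all)
  methods <- toupper(methods)
  bad <- setdiff(methods, all)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  methods
}

# features table -> standardized design matrix + label factor
clf_xy <- function(features) {
  x <- as.matrix(features[, feature_names()])
  y <- factor(features$label, levels = c("low", "high"))
  if (anyNA(y)) stop("unlabelled beats in the classifier input")
  list(x = x, y = y)
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(mu = mu, sd = sdev)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2L, st$mu, "-"), 2L, st$sd, "/")
}

# fit one method on (xtr, ytr) and return positive-class ("high")
# probabilities for xte; xtr/xte are already standardized
fit_predict_clf <- function(method, xtr, ytr, xte, hp, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  p <- switch(method,
    SVM = {
      fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial",
                        cost = hp$svm_cost, probability = TRUE, scale = FALSE)
      attr(predict(fit, xte, probability = TRUE), "probabilities")[, "high"]
    },
    MLP = {
      fit <- nnet::nnet(x = xtr, y = as.numeric(ytr == "high"),
                        size = hp$mlp_size, maxit = hp$mlp_maxit,
                        decay = hp$mlp_decay, entropy = TRUE,
                        trace = FALSE, MaxNWts = 10000)
      as.numeric(predict(fit, xte))
    },
    GNB = {
      fit <- e1071::naiveBayes(x = as.data.frame(xtr), y = ytr)
      predict(fit, as.data.frame(xte), type = "raw")[, "high"]
    },
    DT = {
      dtr <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class",
                          control = rpart::rpart.control(
                            cp = hp$dt_cp, minsplit = hp$dt_minsplit,
                            xval = 0))
      predict(fit, data.frame(xte, check.names = FALSE))[, "high"]
    },
    RF = {
      fit <- ranger::ranger(x = xtr, y = ytr, num.trees = hp$rf_trees,
                            probability = TRUE, num.threads = 1,
                            seed = as.integer(seed %% .Machine$integer.max))
      predict(fit, data = xte, num.threads = 1)$predictions[, "high"]
    },
    LR = {
      dtr <- data.frame(.y = as.numeric(ytr == "high"), xtr,
                        check.names = FALSE)
      fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
      suppressWarnings(as.numeric(
        predict(fit, data.frame(xte, check.names = FALSE),
                type = "response")))
    },
    LDA = {
      fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr))
      predict(fit, xte)$posterior[, "high"]
    },
    KNN = {
      pred <- class::knn(train = xtr, test = xte, cl = ytr,
                         k = hp$knn_k, prob = TRUE)
      pw <- attr(pred, "prob")
      ifelse(pred == "high", pw, 1 - pw)
    },
    stop("unknown method: ", method))
  as.numeric(p)
}

# threshold beat scores at 0.5 (ties conservatively called low quality)
score_confusion <- function(scores, truth) {
  pred_high <- scores > 0.5
  truth_high <- truth == "high"
  c(TP = sum(pred_high & truth_high), FN = sum(!pred_high & truth_high),
    TN = sum(!pred_high & !truth_high), FP = sum(pred_high & !truth_high))
}

eval_row <- function(method, fold, cm, scores, truth) {
  m <- confusion_metrics(cm["TP"], cm["FN"], cm["TN"], cm["FP"])
  data.frame(method = method, fold = fold,
             TP = unname(cm["TP"]), FN = unname(cm["FN"]),
             TN = unname(cm["TN"]), FP = unname(cm["FP"]),
             accuracy = m$accuracy,
             sensitivity = m$sensitivity / 100,
             specificity = m$specificity / 100,
             auc = roc_auc(scores, truth, positive = "high"),
             stringsAsFactors = FALSE)
}

average_rows <- function(rows, label = "Average") {
  data.frame(method = rows$method[1L], fold = label,
             TP = NA_real_, FN = NA_real_, TN = NA_real_, FP = NA_real_,
             accuracy = mean(rows$accuracy),
             sensitivity = mean(rows$sensitivity),
             specificity = mean(rows$specificity),
             auc = mean(rows$auc), stringsAsFactors = FALSE)
}

new_pulse_eval <- function(protocol, metrics, seed, n_units, unit = "beat") {
  structure(list(protocol = protocol, metrics = metrics, seed = seed,
                 n_units = n_units, unit = unit,
                 methods = unique(metrics$method)),
            class = "pulse_eval")
}

#' Threefold cross-validated quality classification
#'
#' Evaluates the chosen classifiers by threefold cross-validation on the
#' beat feature table, stratified by class at the beat level by default
#' (set `group_by_subject = TRUE` to keep each subject's beats in one fold
#' instead). Features are standardized inside each fold using training
#' statistics only. With `select = TRUE` (default) the input is first
#' reduced to the expert-selected pools via [select_quality_beats()].
#'
#' @param features a [build_feature_table()] result.
#' @param methods `"all"` or a character vector of method names (see
#'   [classifiers]).
#' @param seed integer seed for fold assignment and stochastic fits.
#' @param group_by_subject assign whole subjects to folds.
#' @param select apply [select_quality_beats()] first.
#' @param hyperparams named list of hyperparameter overrides.
#' @return A `pulse_eval` object; `$metrics` has rows for folds 1-3 and
#'   the average, per method, with confusion counts, accuracy (percent),
#'   sensitivity, specificity (proportions) and AUC.
#' @export
train_eval_threefold <- function(features, methods = "all", seed = 1,
                                 group_by_subject = FALSE, select = TRUE,
                                 hyperparams = list()) {
  methods <- resolve_methods(methods)
  hp <- default_hyperparams(hyperparams)
  if (select) features <- select_quality_beats(features)
  xy <- clf_xy(features)
  if (nlevels(droplevels(xy$y)) < 2L)
    stop("both quality classes must be present")
  n_subj <- tapply(features$subject, xy$y, function(s) length(unique(s)))
  if (any(is.na(n_subj)) || any(n_subj < 3L))
    warning("fewer than 3 subjects per class: fold estimates may be unstable")

  with_seed(seed, {
  fold <- integer(nrow(features))
  if (group_by_subject) {
    subj <- unique(features$subject)
    assign <- setNames(rep_len(1:3, length(subj)), sample(subj))
    fold <- assign[features$subject]
  } else {
    for (cls in levels(xy$y)) {
      idx <- sample(which(xy$y == cls))
      fold[idx] <- rep_len(1:3, length(idx))
    }
  }

  rows <- list()
  for (f in 1:3) {
    tr <- fold != f
    te <- fold == f
    if (nlevels(droplevels(xy$y[tr])) < 2L || nlevels(droplevels(xy$y[te])) < 2L)
      stop("a class is absent from fold ", f,
           "; use more data or beat-level stratification")
    st <- standardize_fit(xy$x[tr, , drop = FALSE])
    xtr <- standardize_apply(xy$x[tr, , drop = FALSE], st)
    xte <- standardize_apply(xy$x[te, , drop = FALSE], st)
    for (m in methods) {
      p <- fit_predict_clf(m, xtr, xy$y[tr], xte, hp,
                           seed = seed + 101 * f + 7919 * match(m, clf_method_names()))
      cm <- score_confusion(p, as.character(xy$y[te]))
      rows[[paste(m, f)]] <- eval_row(m, as.character(f), cm, p,
                                      as.character(xy$y[te]))
    }
  }
  metrics <- do.call(rbind, unname(rows))
  metrics <- do.call(rbind, c(
    lapply(methods, function(m) {
      mr <- metrics[metrics$method == m, , drop = FALSE]
      rbind(mr, average_rows(mr))
    })))
  rownames(metrics) <- NULL
  new_pulse_eval("threefold", metrics, seed, nrow(features))
  })
}

#' Leave-one-subject-out quality classification
#'
#' For each subject in turn, the classifiers are trained on every other
#' subject's expert-selected beats and predict all beats of the held-out
#' subject's recordings. Subject-id bookkeeping forbids any held-out beat
#' (including duplicated rows of that subject) from entering the training
#' pool. By default each held-out recording then receives a single
#' predicted label by majority vote over its beat predictions (ties called
#' low quality), the truth label of a recording being high quality for the
#' appropriate-pressure condition and low quality for the higher-pressure
#' condition; confusion counts accumulate over recordings and the AUC is
#' computed from the recording-level fractions of beats predicted high
#' quality. `unit = "beat"` instead counts individual beats against their
#' own truth labels.
#'
#' @inheritParams train_eval_threefold
#' @param unit evaluation unit: `"recording"` (default) or `"beat"`.
#' @return A `pulse_eval` object with one row per method; with
#'   `unit = "recording"`, `$recording_scores` holds, per method, the
#'   recording identifiers with their predicted-high fractions and truth
#'   labels (the inputs to the reported AUC, e.g. for permutation nulls or
#'   ROC plots).
#' @export
leave_one_subject_out <- function(features, methods = "all", seed = 1,
                                  unit = c("recording", "beat"),
                                  select = TRUE, hyperparams = list()) {
  unit <- match.arg(unit)
  methods <- resolve_methods(methods)
  hp <- default_hyperparams(hyperparams)
  pool <- if (select) select_quality_beats(features) else features
  subjects <- unique(features$subject)
  if (length(subjects) < 3L)
    warning("fewer than 3 subjects: leave-one-subject-out estimates are unstable")

  with_seed(seed, {
  scores <- matrix(NA_real_, nrow(features), length(methods),
                   dimnames = list(NULL, methods))
  for (s in subjects) {
    tr <- pool[pool$subject != s, , drop = FALSE]
    stopifnot(!any(tr$subject == s))  # leakage guard
    te_idx <- which(features$subject == s)
    xy_tr <- clf_xy(tr)
    st <- standardize_fit(xy_tr$x)
    xtr <- standardize_apply(xy_tr$x, st)
    xte <- standardize_apply(as.matrix(features[te_idx, feature_names()]), st)
    for (m in methods) {
      scores[te_idx, m] <- fit_predict_clf(
        m, xtr, xy_tr$y, xte, hp,
        seed = seed + 7919 * match(m, clf_method_names()) +
          101 * match(s, subjects))
    }
  }

  rec_scores <- list()
  rows <- lapply(methods, function(m) {
    if (unit == "beat") {
      cm <- score_confusion(scores[, m], features$label)
      eval_row(m, "LOSO", cm, scores[, m], features$label)
    } else {
      key <- paste(features$subject, features$regime)
      frac <- tapply(scores[, m] > 0.5, key, mean)
      truth <- tapply(seq_len(nrow(features)), key, function(i) {
        rg <- features$regime[i[1L]]
        if (rg %in% c("appropriate", "higher")) {
          if (rg == "appropriate") "high" else "low"
        } else {
          # no regime metadata: recording truth is its majority beat label
          if (mean(features$label[i] == "high") > 0.5) "high" else "low"
        }
      })
      truth <- truth[names(frac)]
      pred <- ifelse(frac > 0.5, "high", "low")
      cm <- c(TP = sum(pred == "high" & truth == "high"),
              FN = sum(pred == "low" & truth == "high"),
              TN = sum(pred == "low" & truth == "low"),
              FP = sum(pred == "high" & truth == "low"))
      rec_scores[[m]] <<- data.frame(recording = names(frac),
                                     score = as.numeric(frac),
                                     truth = as.character(truth),
                                     stringsAsFactors = FALSE)
      eval_row(m, "LOSO", cm, as.numeric(frac), as.character(truth))
    }
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  n_units <- if (unit == "beat") nrow(features) else
    length(unique(paste(features$subject, features$regime)))
  out <- new_pulse_eval("loso", metrics, seed, n_units, unit)
  if (unit == "recording") out$recording_scores <- rec_scores
  out
  })
}

#' Subject-grouped 8:2 hold-out evaluation
#'
#' Splits the subjects (not beats) into a training portion and a hold-out
#' portion, runs threefold cross-validation on the training portion
#' (rows 1-3 and their average), then trains on the full training portion
#' and evaluates once on the held-out subjects' selected beats (row
#' `"Holdout"`).
#'
#' @inheritParams train_eval_threefold
#' @param split fraction of subjects in the training portion, default 0.8.
#' @return A `pulse_eval` object with rows 1-3, Average and Holdout per
#'   method.
#' @export
holdout_eval <- function(features, methods = "all", seed = 1, split = 0.8,
                         select = TRUE, hyperparams = list()) {
  if (split <= 0 || split >= 1) stop("'split' must lie in (0, 1)")
  methods <- resolve_methods(methods)
  hp <- default_hyperparams(hyperparams)
  sel <- if (select) select_quality_beats(features) else features

  subjects <- unique(sel$subject)
  with_seed(seed, {
  n_tr <- max(1L, round(split * length(subjects)))
  if (n_tr >= length(subjects)) stop("'split' leaves no hold-out subjects")
  tr_subj <- sample(subjects, n_tr)
  tr <- sel[sel$subject %in% tr_subj, , drop = FALSE]
  te <- sel[!sel$subject %in% tr_subj, , drop = FALSE]
  if (length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L)
    stop("the hold-out split leaves a class empty; use more subjects")

  cv <- train_eval_threefold(tr, methods = methods, seed = seed,
                             select = FALSE, hyperparams = hyperparams)
  xy_tr <- clf_xy(tr)
  st <- standardize_fit(xy_tr$x)
  xtr <- standardize_apply(xy_tr$x, st)
  xte <- standardize_apply(as.matrix(te[, feature_names()]), st)
  hold <- lapply(methods, function(m) {
    p <- fit_predict_clf(m, xtr, xy_tr$y, xte, hp,
                         seed = seed + 7919 * match(m, clf_method_names()))
    cm <- score_confusion(p, te$label)
    eval_row(m, "Holdout", cm, p, te$label)
  })
  hold <- do.call(rbind, hold)
  metrics <- do.call(rbind, lapply(methods, function(m) {
    rbind(cv$metrics[cv$metrics$method == m, , drop = FALSE],
          hold[hold$method == m, , drop = FALSE])
  }))
  rownames(metrics) <- NULL
  out <- new_pulse_eval("holdout", metrics, seed, nrow(sel))
  out$train_subjects <- sort(tr_subj)
  out
  })
}

#' Evaluate pulse-quality classifiers
#'
#' Umbrella for the three evaluation protocols: `"threefold"`
#' cross-validation ([train_eval_threefold()]), `"loso"`
#' leave-one-subject-out testing ([leave_one_subject_out()]) and the
#' subject-grouped `"holdout"` 8:2 split ([holdout_eval()]).
#'
#' @param features a [build_feature_table()] result.
#' @param protocol one of `"threefold"`, `"loso"`, `"holdout"`.
#' @param ... passed to the protocol function (`methods`, `seed`,
#'   `select`, `hyperparams`, and protocol-specific arguments).
#' @return A `pulse_eval` object.
#' @export
#' @seealso [classifiers]
quality_eval <- function(features, protocol = c("threefold", "loso", "holdout"),
                         ...) {
  protocol <- match.arg(protocol)
  switch(protocol,
         threefold = train_eval_threefold(features, ...),
         loso = leave_one_subject_out(features, ...),
         holdout = holdout_eval(features, ...))
}

#' @export
print.pulse_eval <- function(x, digits = 2, ...) {
  hdr <- c(threefold = "Threefold cross-validation",
           loso = "Leave-one-subject-out test",
           holdout = "Subject-grouped 8:2 hold-out")
  cat(hdr[[x$protocol]], sprintf("(%d %ss)\n", x$n_units, x$unit))
  if (x$protocol == "loso") {
    cols <- c("TP", "FN", "TN", "FP")
    counts <- t(as.matrix(x$metrics[, cols]))
    colnames(counts) <- x$metrics$method
    print(counts)
    disp <- rbind(`Sensitivity (%)` = 100 * x$metrics$sensitivity,
                  `Specificity (%)` = 100 * x$metrics$specificity,
                  `Accuracy (%)` = x$metrics$accuracy,
                  `AUC of ROC` = x$metrics$auc)
    colnames(disp) <- x$metrics$method
    print(round(disp, digits))
  } else {
    for (metric in c("accuracy", "sensitivity", "specificity", "auc")) {
      cat("\n", switch(metric, accuracy = "Accuracy (%)",
                       sensitivity = "Sensitivity", specificity = "Specificity",
                       auc = "AUC"), "\n", sep = "")
      tab <- tapply(x$metrics[[metric]],
                    list(x$metrics$fold, x$metrics$method), identity)
      folds <- unique(x$metrics$fold)
      print(round(tab[folds, x$methods, drop = FALSE], digits))
    }
  }
  invisible(x)
}

#' @export
summary.pulse_eval <- function(object, ...) {
  key <- if (object$protocol == "threefold") "Average"
         else if (object$protocol == "holdout") c("Average", "Holdout")
         else "LOSO"
  out <- object$metrics[object$metrics$fold %in% key,
                        c("method", "fold", "accuracy", "sensitivity",
                          "specificity", "auc")]
  rownames(out) <- NULL
  out
}

#' @export
plot.pulse_eval <- function(x, metric = "auc", ...) {
  s <- summary(x)
  s <- s[s$fold %in% c("Average", "LOSO", "Holdout"), ]
  s <- s[!duplicated(s$method), ]
  barplot(s[[metric]], names.arg = s$method, ylab = toupper(metric),
          main = sprintf("%s (%s)", toupper(metric), x$protocol),
          ylim = c(0, if (metric == "accuracy") 100 else 1), ...)
  invisible(x)
}
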
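#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity from binary confusion counts,
#' following the usual conventions for a quality screen where "positive"
#' means a high-quality pulse:
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#' All three are returned as percentages at full precision; round for
#' display. An undefined metric (zero denominator) is `NA`.
#'
#' @param TP,FN,TN,FP non-negative counts; alternatively pass a single
#'   named vector/list as `TP`.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`
#'   (percent).
#' @export
#' @examples
#' confusion_metrics(TP = 24, FN = 6, TN = 29, FP = 1)
confusion_metrics <- function(TP, FN = NULL, TN = NULL, FP = NULL) {
  if (is.null(FN) && (is.list(TP) || length(TP) == 4L)) {
    cm <- as.list(TP)
    TP <- cm$TP; FN <- cm$FN; TN <- cm$TN; FP <- cm$FP
  }
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("confusion counts must be finite and non-negative")
  total <- TP + FN + TN + FP
  if (total == 0) stop("empty confusion matrix")
  list(accuracy = 100 * (TP + TN) / total,
       sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' randomly chosen positive unit scores higher than a randomly chosen
#' negative unit, with ties counted one half. This equals the trapezoidal
#' integral of the ROC curve.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels class labels; `positive` identifies the positive level.
#'   Logical and 0/1 labels are also accepted (`TRUE`/`1` positive).
#' @param positive the positive class label, default `"high"`.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), positive = 1)
roc_auc <- function(scores, labels, positive = "high") {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length")
  pos <- if (is.logical(labels)) labels else labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare one harmonic index between two groups
#'
#' Two-sided Welch unequal-variance comparison of an index between two
#' groups (optionally paired, since the two contact pressures were
#' measured on the same subjects), with the significance flag convention
#' used throughout the package's group figures: `"*"` for p < 0.05, `"+"`
#' for 0.05 < p < 0.1, empty otherwise.
#'
#' @param values_a,values_b numeric vectors of index values for the two
#'   groups (each of length >= 2).
#' @param index index name for the output row.
#' @param paired use a paired test (`values_a` and `values_b` must then be
#'   equal-length and subject-aligned).
#' @return A one-row data frame of class `group_comparison`: `index`,
#'   `n_a`, `mean_a`, `sd_a`, `n_b`, `mean_b`, `sd_b`, `p_value`, `flag`.
#' @export
group_compare <- function(values_a, values_b, index = "", paired = FALSE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  p <- tryCatch(
    t.test(values_a, values_b, paired = paired, var.equal = FALSE)$p.value,
    error = function(e) {
      # degenerate constant data: identical groups are indistinguishable
      if (isTRUE(all.equal(mean(values_a), mean(values_b)))) 1 else 0
    })
  flag <- if (p < 0.05) "*" else if (p > 0.05 && p < 0.1) "+" else ""
  structure(data.frame(index = index,
                       n_a = length(values_a), mean_a = mean(values_a),
                       sd_a = sd(values_a),
                       n_b = length(values_b), mean_b = mean(values_b),
                       sd_b = sd(values_b),
                       p_value = p, flag = flag,
                       stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' Group comparison of all 40 indices
#'
#' Runs [group_compare()] on every harmonic index between the two levels
#' of a grouping column, the in-package analogue of the figure comparing
#' index means between contact pressures (`by = "regime"`) or between
#' expert quality classes (`by = "label"`). Group A is the
#' appropriate-pressure / high-quality level, group B the other.
#'
#' @param features a [build_feature_table()] result.
#' @param by `"regime"` or `"label"`.
#' @param collapse `"record"` (default) averages each index within each
#'   recording first, so recordings are the sampling units; `"beat"` pools
#'   individual beats.
#' @param paired passed to [group_compare()] (only meaningful with
#'   `collapse = "record"` and complete subject pairing).
#' @return Data frame with one row per index (40 rows).
#' @export
compare_indices <- function(features, by = c("regime", "label"),
                            collapse = c("record", "beat"), paired = FALSE) {
  by <- match.arg(by)
  collapse <- match.arg(collapse)
  lev_a <- if (by == "regime") "appropriate" else "high"
  lev_b <- if (by == "regime") "higher" else "low"
  dat <- features[features[[by]] %in% c(lev_a, lev_b), , drop = FALSE]
  if (collapse == "record") {
    dat <- aggregate(dat[feature_names()],
                     by = list(subject = dat$subject, regime = dat$regime,
                               group = dat[[by]]),
                     FUN = mean)
  } else {
    dat$group <- dat[[by]]
  }
  rows <- lapply(feature_names(), function(fn) {
    group_compare(dat[[fn]][dat$group == lev_a],
                  dat[[fn]][dat$group == lev_b],
                  index = fn, paired = paired)
  })
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  attr(out, "groups") <- c(a = lev_a, b = lev_b)
  out
}

#' Recording duration needed for a pulse count
#'
#' How long a wearable device must record to accumulate a given number of
#' pulses at a given heart rate: `n_pulses / hr * 60` seconds. For
#' example, 30 pulses at 72 beats/min require 30/72 x 60 = 25 s.
#'
#' @param n_pulses number of pulses required (>= 0).
#' @param hr heart rate in beats/min (> 0).
#' @return Duration in seconds.
#' @export
#' @examples
#' recording_duration(30, 72)  # 25
recording_duration <- function(n_pulses, hr) {
  if (any(hr <= 0)) stop("'hr' must be positive")
  if (any(n_pulses < 0)) stop("'n_pulses' must be non-negative")
  n_pulses / hr * 60
}
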
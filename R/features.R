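#' Harmonic decomposition of a single beat
#'
#' Projects one beat onto the cosine series
#' \eqn{x_k \approx dc + \sum_{n=1}^{10} a_n \cos(2\pi n k/N + \phi_n \pi/180)}
#' whose fundamental is one cycle per beat (fundamental frequency
#' `1/period`). Because a beat segment holds exactly one period in `N`
#' samples, the projection is the discrete Fourier transform restricted to
#' bins 1..10: \eqn{a_n = 2|X_n|/N}, \eqn{\phi_n = \arg X_n}, with phases
#' reported in degrees wrapped to \eqn{(-180, 180]}.
#'
#' @param beat a `beat_segment` or a numeric vector of samples covering one
#'   beat period.
#' @param n_harmonics number of harmonics, default (and maximum used by the
#'   feature set) 10.
#' @return An object of class `harmonic_decomposition` with fields `dc`,
#'   `amplitudes` and `phases`.
#' @export
#' @examples
#' x <- synthesize_beat(harmonic_template(), period = 0.8, sampling_rate = 1024)
#' decompose_beat(x)$amplitudes
decompose_beat <- function(beat, n_harmonics = 10L) {
  x <- if (inherits(beat, "beat_segment")) beat$samples else as.numeric(beat)
  n <- length(x)
  if (n < 2L * n_harmonics + 1L)
    stop("beat too short: need at least 2 * n_harmonics + 1 samples")
  X <- fft(x)
  idx <- seq_len(n_harmonics) + 1L
  amp <- 2 * Mod(X[idx]) / n
  ph <- wrap_deg(Arg(X[idx]) * 180 / pi)
  ph[amp == 0] <- 0
  structure(list(dc = Re(X[1L]) / n, amplitudes = amp, phases = ph),
            class = "harmonic_decomposition")
}

#' @export
print.harmonic_decomposition <- function(x, ...) {
  cat("Harmonic decomposition (", length(x$amplitudes), " harmonics)\n", sep = "")
  print(data.frame(n = seq_along(x$amplitudes),
                   amplitude = signif(x$amplitudes, 4),
                   phase_deg = signif(x$phases, 4)), row.names = FALSE)
  invisible(x)
}

#' Amplitude proportions C1..C10
#'
#' The nth amplitude proportion is the nth harmonic amplitude expressed as
#' a fraction of the beat's harmonic content. The default denominator is
#' the total harmonic amplitude \eqn{\sum_{k=1}^{10} a_k}, so the
#' proportions sum to one; `normalization = "fundamental"` divides by
#' \eqn{a_1} instead.
#'
#' @param decomposition a [decompose_beat()] result.
#' @param normalization `"total"` (default) or `"fundamental"`.
#' @return Numeric vector `C1..C10`.
#' @export
amplitude_proportions <- function(decomposition,
                                  normalization = c("total", "fundamental")) {
  normalization <- match.arg(normalization)
  a <- decomposition$amplitudes
  denom <- if (normalization == "total") sum(a) else a[1L]
  if (!is.finite(denom) || denom <= 0)
    stop("undefined amplitude proportions: zero harmonic content")
  a / denom
}

#' Phase angles P1..P10
#'
#' Returns the harmonic phase angles in degrees, wrapped to
#' \eqn{(-180, 180]}, relative to the beat-onset time origin of the cosine
#' series. The phase of a zero-amplitude harmonic is undefined and
#' reported as `NA` (such beats are excluded from phase statistics by
#' [build_feature_table()]).
#'
#' @param decomposition a [decompose_beat()] result.
#' @return Numeric vector `P1..P10` (degrees), `NA` where the harmonic
#'   amplitude is zero.
#' @export
phase_angles <- function(decomposition) {
  p <- wrap_deg(decomposition$phases)
  a <- decomposition$amplitudes
  # a harmonic that is zero up to numerical noise has no meaningful phase
  p[a <= 1e-9 * max(a, 0)] <- NA_real_
  p
}

#' Beat-to-beat variability indices CV_n and P_n_SD
#'
#' Given the per-beat series of one record's amplitude proportions (or
#' phase angles), computes for each beat the coefficient of variation
#' `CV_n = 100 * SD / mean` (in percent, `type = "cv"`) or the standard
#' deviation of the unwrapped phase sequence in degrees (`type = "sd"`),
#' over a window of beats. The default window `"record"` uses every beat
#' in the record, so all beats of a record share the record-level
#' statistic; an odd integer `window` instead uses a sliding window of
#' that many beats centred on each beat (truncated at the record edges).
#' Sample statistics use the `n - 1` denominator. Windows with fewer than
#' two beats, or a zero-mean window for `"cv"`, yield `NA`.
#'
#' @param series numeric matrix, beats in rows and harmonics 1..10 in
#'   columns: C_n values for `type = "cv"`, P_n values (degrees) for
#'   `type = "sd"`.
#' @param window `"record"` or an odd integer window width in beats.
#' @param type `"cv"` for CV_n (percent) or `"sd"` for P_n_SD (degrees).
#' @return Matrix of the same shape as `series`.
#' @export
windowed_variability <- function(series, window = "record",
                                 type = c("cv", "sd")) {
  type <- match.arg(type)
  series <- as.matrix(series)
  nb <- nrow(series)
  if (nb < 2L) stop("variability indices need at least 2 beats")

  stat_fun <- function(v) {
    if (type == "cv") {
      m <- mean(v)
      if (!is.finite(m) || m == 0) return(NA_real_)
      100 * sd(v) / m
    } else {
      sd(unwrap_deg(v))
    }
  }

  out <- matrix(NA_real_, nb, ncol(series))
  if (identical(window, "record")) {
    rec <- apply(series, 2L, stat_fun)
    out <- matrix(rec, nb, ncol(series), byrow = TRUE)
  } else {
    w <- as.integer(window)
    if (w < 2L) stop("'window' must be 'record' or an integer >= 2")
    half <- w %/% 2L
    for (i in seq_len(nb)) {
      lo <- max(1L, i - half)
      hi <- min(nb, i + half)
      if (hi - lo + 1L < 2L) next
      out[i, ] <- apply(series[lo:hi, , drop = FALSE], 2L, stat_fun)
    }
  }
  dimnames(out) <- dimnames(series)
  out
}

feature_names <- function() {
  c(paste0("C", 1:10), paste0("CV", 1:10),
    paste0("P", 1:10), paste0("P", 1:10, "_SD"))
}

#' Build the 40-index beat feature table
#'
#' Segments every record into beats and computes, per retained beat, the
#' 40 harmonic indices: amplitude proportions C1..C10, their beat-to-beat
#' coefficients of variation CV1..CV10 (percent), phase angles P1..P10
#' (degrees), and the phase standard deviations P1_SD..P10_SD (degrees).
#' Beats with any undefined feature are dropped and counted in the
#' `n_dropped` attribute.
#'
#' For synthetic records (`use_truth = TRUE`, the default when ground truth
#' is present) segmentation uses the generator's true beat boundaries and
#' labels. Otherwise onsets come from [detect_beat_onsets()] and labels
#' from the `annotations` table (columns `subject`, `regime`, `beat_index`,
#' `label`) when supplied, or from the nearest truth onset within 25 ms.
#'
#' @param records a `pulse_cohort`, a list of `pulse_record`s, or a single
#'   record.
#' @param window variability window passed to [windowed_variability()].
#' @param normalization passed to [amplitude_proportions()].
#' @param use_truth use generator ground-truth onsets/labels when present.
#' @param annotations optional per-beat quality annotation data frame.
#' @param ... further arguments passed to [detect_beat_onsets()].
#' @return A data frame of class `pulse_features` with columns `subject`,
#'   `regime`, `beat_index`, `label`, then the 40 feature columns
#'   `C1..C10, CV1..CV10, P1..P10, P1_SD..P10_SD`. Attributes: `window`,
#'   `normalization`, `n_dropped`.
#' @export
build_feature_table <- function(records, window = "record",
                                normalization = c("total", "fundamental"),
                                use_truth = TRUE, annotations = NULL, ...) {
  normalization <- match.arg(normalization)
  if (inherits(records, "pulse_record")) records <- list(records)
  if (!length(records)) stop("empty cohort: no records to featurize")

  per_record <- vector("list", length(records))
  n_dropped <- 0L
  for (r in seq_along(records)) {
    rec <- records[[r]]
    truth_ok <- use_truth && !is.null(rec$truth_onsets) &&
      length(rec$truth_onsets) >= 2L
    if (truth_ok) {
      # truth onsets tile the record: close the last beat at the record end
      onsets <- c(rec$truth_onsets, length(rec$samples) + 1L)
      labels_all <- rec$truth_beat_labels
    } else {
      onsets <- detect_beat_onsets(rec, ...)
      labels_all <- NULL
    }
    beats <- segment_beats(rec, onsets)
    if (length(beats) < 2L) {
      warning("record ", rec$subject_id, "/", rec$regime,
              " has fewer than 2 usable beats; skipped")
      next
    }
    nb <- length(beats)
    C <- matrix(NA_real_, nb, 10L)
    P <- matrix(NA_real_, nb, 10L)
    ok <- rep(TRUE, nb)
    for (i in seq_len(nb)) {
      dec <- decompose_beat(beats[[i]])
      ci <- tryCatch(amplitude_proportions(dec, normalization),
                     error = function(e) NULL)
      if (is.null(ci)) { ok[i] <- FALSE; next }
      C[i, ] <- ci
      P[i, ] <- phase_angles(dec)
    }
    if (sum(ok) < 2L) {
      warning("record ", rec$subject_id, "/", rec$regime,
              " has fewer than 2 decomposable beats; skipped")
      n_dropped <- n_dropped + nb
      next
    }
    CV <- windowed_variability(C[ok, , drop = FALSE], window, "cv")
    PSD <- windowed_variability(P[ok, , drop = FALSE], window, "sd")

    idx <- vapply(beats, `[[`, integer(1), "beat_index")
    label <- if (!is.null(labels_all)) {
      labels_all[idx]
    } else if (!is.null(annotations)) {
      key <- paste(rec$subject_id, rec$regime, idx)
      ann_key <- paste(annotations$subject, annotations$regime,
                       annotations$beat_index)
      as.character(annotations$label[match(key, ann_key)])
    } else if (!is.null(rec$truth_onsets)) {
      # detected beats matched to the nearest truth onset within 25 ms
      tol <- 0.025 * rec$sampling_rate
      on <- vapply(beats, `[[`, integer(1), "onset")
      near <- vapply(on, function(o) {
        j <- which.min(abs(rec$truth_onsets - o))
        if (abs(rec$truth_onsets[j] - o) <= tol) j else NA_integer_
      }, integer(1))
      rec$truth_beat_labels[near]
    } else rep(NA_character_, nb)

    df <- data.frame(subject = rec$subject_id, regime = rec$regime,
                     beat_index = idx, label = label,
                     stringsAsFactors = FALSE)[ok, , drop = FALSE]
    feat <- cbind(C[ok, , drop = FALSE], CV, P[ok, , drop = FALSE], PSD)
    colnames(feat) <- feature_names()
    df <- cbind(df, feat)
    complete <- stats::complete.cases(df[, feature_names()])
    n_dropped <- n_dropped + sum(!ok) + sum(!complete)
    per_record[[r]] <- df[complete, , drop = FALSE]
  }
  out <- do.call(rbind, per_record)
  if (is.null(out) || !nrow(out)) stop("no usable beats in the cohort")
  rownames(out) <- NULL
  if (n_dropped > 0)
    message(n_dropped, " beat(s) dropped for undefined features")
  structure(out, class = c("pulse_features", "data.frame"),
            window = window, normalization = normalization,
            n_dropped = n_dropped)
}

#' Emulate expert selection of classifier training pulses
#'
#' Keeps the high-quality beats of appropriate-pressure recordings and the
#' low-quality beats of higher-pressure recordings — the two expert-curated
#' pulse pools used to train and cross-validate the quality classifiers.
#'
#' @param features a [build_feature_table()] result.
#' @return The filtered feature table.
#' @export
select_quality_beats <- function(features) {
  keep <- (features$regime == "appropriate" & features$label == "high") |
    (features$regime == "higher" & features$label == "low")
  keep[is.na(keep)] <- FALSE
  features[keep, , drop = FALSE]
}
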
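#' Detect beat onsets (pulse feet) in a continuous recording
#'
#' Slope-threshold foot detection: the smoothed first derivative of the
#' pressure signal is thresholded at `slope_k` times its robust spread
#' (median absolute deviation); each suprathreshold systolic upstroke —
#' subject to a refractory period of `60 / max_hr` seconds — is traced
#' backwards to the preceding local minimum of the raw signal, which is
#' taken as the beat onset. Upstrokes whose peak slope is far below the
#' record's typical upstroke slope are rejected, which suppresses spurious
#' detections on diastolic oscillations.
#'
#' @param record a `pulse_record` (or any list with `samples` and
#'   `sampling_rate`).
#' @param min_hr,max_hr physiologic heart-rate gate in beats/min; the
#'   refractory period between detected upstrokes is `60 / max_hr` s.
#' @param slope_k threshold in robust-SD units of the smoothed derivative.
#' @return Strictly increasing integer vector of 1-based onset sample
#'   indices. A flat or onset-free signal yields `integer(0)` with a
#'   warning.
#' @seealso [segment_beats()]
#' @export
detect_beat_onsets <- function(record, min_hr = 30, max_hr = 240,
                               slope_k = 2) {
  x <- record$samples
  fs <- record$sampling_rate
  if (length(x) < 2 * fs) stop("record must be at least 2 s long")
  if (min_hr >= max_hr) stop("'min_hr' must be smaller than 'max_hr'")

  d <- c(diff(x), 0) * fs
  w <- max(3L, as.integer(round(0.005 * fs)))
  dsm <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
  dsm[is.na(dsm)] <- 0
  spread <- mad(dsm)
  thr <- slope_k * spread
  if (spread == 0) {
    # mostly-flat signal (e.g. a single beat on a long baseline): fall back
    # to a fraction of the peak slope
    if (max(dsm) > 0) thr <- 0.5 * max(dsm)
  }
  if (thr <= 0 || all(dsm <= thr)) {
    warning("no beat onsets detected (flat or featureless signal)")
    return(integer(0))
  }

  above <- dsm > thr
  rises <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(rises)) {
    warning("no beat onsets detected")
    return(integer(0))
  }

  # refractory merge: keep the first crossing of each upstroke group
  refractory <- as.integer(round(60 / max_hr * fs))
  keep <- rises[c(TRUE, diff(rises) > refractory)]

  # reject weak upstrokes: peak slope within each group must be comparable
  # to the record-typical upstroke slope
  peak <- vapply(keep, function(u) {
    max(dsm[u:min(u + refractory, length(dsm))])
  }, numeric(1))
  typical <- median(peak)
  keep <- keep[peak >= 0.5 * typical]
  if (!length(keep)) {
    warning("no beat onsets detected")
    return(integer(0))
  }

  # backward search for the local minimum preceding each upstroke
  back <- as.integer(round(0.25 * fs))
  onsets <- vapply(keep, function(u) {
    lo <- max(1L, u - back)
    seg <- x[lo:u]
    # last occurrence of the minimum: on a flat diastolic baseline the foot
    # is the plateau sample adjacent to the upstroke
    lo + max(which(seg == min(seg))) - 1L
  }, integer(1))
  onsets <- sort(unique(onsets))

  # enforce the minimum physiologic gap (keep the earlier onset)
  if (length(onsets) > 1L) {
    min_gap <- as.integer(round(60 / max_hr * fs))
    ok <- c(TRUE, diff(onsets) >= min_gap)
    while (!all(ok)) {
      onsets <- onsets[ok]
      ok <- c(TRUE, diff(onsets) >= min_gap)
    }
  }
  onsets
}

#' Cut a recording into single-beat segments
#'
#' Forms one segment per consecutive pair of onsets, using half-open
#' intervals `[onset_i, onset_{i+1})`. The partial beat before the first
#' onset and after the last onset are discarded. Segments whose implied
#' period falls outside the physiologic gate (0.25-2.0 s by default, i.e.
#' heart rates 30-240 beats/min) are dropped; the number dropped is
#' reported as attribute `n_dropped` and via a message.
#'
#' @param record a `pulse_record` (or list with `samples`, `sampling_rate`,
#'   optionally `subject_id`).
#' @param onsets strictly increasing 1-based onset indices, e.g. from
#'   [detect_beat_onsets()] or the record's `truth_onsets`.
#' @param min_period,max_period physiologic beat-period gate in seconds.
#' @return A list of class `beat_list`; each element is a `beat_segment`
#'   list with `subject_id`, `beat_index` (ordinal before gating), `onset`,
#'   `end` (exclusive), `samples` and `period` (s). Fewer than two onsets
#'   yield an empty list with a warning.
#' @export
segment_beats <- function(record, onsets, min_period = 0.25, max_period = 2.0) {
  fs <- record$sampling_rate
  if (length(onsets) < 2L) {
    warning("fewer than 2 onsets: no complete beats to segment")
    return(structure(list(), class = "beat_list", n_dropped = 0L))
  }
  if (any(diff(onsets) <= 0)) stop("'onsets' must be strictly increasing")
  # the final onset may sit one past the last sample to close the last beat
  if (onsets[1] < 1L || onsets[length(onsets)] > length(record$samples) + 1L)
    stop("'onsets' outside the sample range")
  sid <- if (!is.null(record$subject_id)) record$subject_id else NA_character_

  n_seg <- length(onsets) - 1L
  segs <- vector("list", n_seg)
  keep <- logical(n_seg)
  for (i in seq_len(n_seg)) {
    on <- onsets[i]
    end <- onsets[i + 1L]
    period <- (end - on) / fs
    keep[i] <- period > min_period && period < max_period
    segs[[i]] <- structure(list(subject_id = sid, beat_index = i,
                                onset = on, end = end,
                                samples = record$samples[on:(end - 1L)],
                                period = period),
                           class = "beat_segment")
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " beat(s) dropped by the physiologic period gate")
  structure(segs[keep], class = "beat_list", n_dropped = n_dropped)
}

#' @export
print.beat_list <- function(x, ...) {
  cat(sprintf("%d beat segments", length(x)))
  if (length(x)) {
    p <- vapply(x, `[[`, numeric(1), "period")
    cat(sprintf(" (period %.2f-%.2f s)", min(p), max(p)))
  }
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0) cat(sprintf(", %d dropped by gate", nd))
  cat("\n")
  invisible(x)
}
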
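#' Synthesize one pulse beat from a harmonic template
#'
#' Evaluates the cosine series
#' \eqn{x(t) = dc + \sum_n a_n \cos(2\pi n t/T + \phi_n \pi/180)}
#' at `N = round(period * sampling_rate)` uniformly spaced instants
#' `t_k = k * period / N`, `k = 0..N-1`, covering exactly one full cycle.
#' Tying the sample grid to the cycle (rather than to an absolute clock)
#' makes the beat an exact one-period discrete signal: [decompose_beat()]
#' recovers the template to machine precision, and concatenated beats of
#' varying period remain sampled within 0.5 sample of the nominal rate.
#'
#' @param template a [harmonic_template()].
#' @param period beat period in seconds (> 0).
#' @param sampling_rate sampling rate in Hz; `period * sampling_rate` must
#'   be at least 21 samples so the 10th harmonic is resolved.
#' @return Numeric vector of `round(period * sampling_rate)` pressure
#'   samples.
#' @export
#' @examples
#' tpl <- harmonic_template(dc_level = 0, amplitudes = 1, phases = 0)
#' x <- synthesize_beat(tpl, period = 1, sampling_rate = 1024)
#' x[1]  # cos(0) = 1
synthesize_beat <- function(template, period, sampling_rate) {
  stopifnot(inherits(template, "harmonic_template"))
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("'period' must be a positive number")
  n <- as.integer(round(period * sampling_rate))
  if (n < 21L)
    stop("'sampling_rate' * 'period' must be at least 21 samples")
  synth_core(template$dc_level, template$amplitudes, template$phases, n)
}

# evaluate the cosine series on n uniformly spaced phase points of one cycle
synth_core <- function(dc, amplitudes, phases, n) {
  theta <- 2 * pi * (0:(n - 1L)) / n
  active <- which(amplitudes > 0)
  x <- rep(dc, n)
  for (h in active)
    x <- x + amplitudes[h] * cos(h * theta + phases[h] * pi / 180)
  x
}

# per-beat motion-artifact channels ---------------------------------------

# additive low-frequency sinusoidal drift across the beat
artifact_drift <- function(x, fs, amp_scale) {
  n <- length(x)
  f <- runif(1, 0.3, 0.8)
  a <- runif(1, 0.2, 0.5) * amp_scale
  psi <- runif(1, 0, 2 * pi)
  x + a * sin(2 * pi * f * (0:(n - 1L)) / fs + psi)
}

# additive transient Gaussian spike inside the beat
artifact_spike <- function(x, fs, amp_scale) {
  n <- length(x)
  centre <- runif(1, 0.15, 0.85) * n
  width <- runif(1, 0.010, 0.030) * fs
  a <- sample(c(-1, 1), 1L) * runif(1, 0.5, 1.5) * amp_scale
  x + a * exp(-((0:(n - 1L)) - centre)^2 / (2 * width^2))
}

#' Simulate one subject-condition recording
#'
#' Concatenates beats whose periods are drawn around the subject's heart
#' rate (Gaussian beat-to-beat period variability, CV 3%, truncated at
#' +/- 3 SD), applies the regime's amplitude jitter (all harmonics) and
#' phase jitter (harmonics 2-10; beats are foot-aligned, so the
#' fundamental's phase is anchored to the onset) to the harmonic template
#' of each beat, and distorts each beat independently
#' with the regime's `artifact_rate` (so realized clean fractions follow
#' the configured quality mixture). Distorted beats are labelled `"low"`,
#' clean beats `"high"`. Three distortion channels are implemented:
#' `baseline_drift` (additive 0.3-0.8 Hz sinusoid), `spike` (transient
#' Gaussian bump, 10-30 ms wide) and `damping` (harmonics 4-10 attenuated
#' to 20-60% with extra phase scatter).
#'
#' The record stops at the last complete beat that fits into `duration`
#' seconds, so every sample belongs to a labelled beat and the ground-truth
#' onsets tile the record exactly.
#'
#' @param config a [sim_config()].
#' @param subject_id subject identifier string.
#' @param regime `"appropriate"` or `"higher"`.
#' @param hr optional subject heart rate in beats/min; drawn from the
#'   configured heart-rate distribution when `NULL`.
#' @param seed optional integer seed for this record; when `NULL` the
#'   current RNG state is used.
#' @return An object of class `pulse_record`: a list with `subject_id`,
#'   `regime`, `sampling_rate`, `samples`, `truth_onsets` (1-based sample
#'   index of each beat's first sample), `truth_beat_labels`
#'   (`"high"`/`"low"` per beat), `hr`, and `jitter_mag` (per-beat mean
#'   absolute relative amplitude perturbation, used to verify regime
#'   separation).
#' @seealso [generate_cohort()]
#' @export
generate_record <- function(config, subject_id, regime = c("appropriate", "higher"),
                            hr = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  regime <- match.arg(regime)
  spec <- config$regimes[[regime]]
  fs <- config$sampling_rate
  with_seed(seed, {
  if (is.null(hr)) hr <- rnorm_trunc(1, config$hr_mean, config$hr_sd)
  total <- round(config$duration * fs)
  mean_period <- 60 / hr
  if (round(mean_period * fs * (1 - 3 * 0.03)) > total)
    stop("'duration' too short to hold a single beat at this heart rate")

  tpl <- spec$template
  samples <- vector("list", ceiling(config$duration / mean_period) + 8L)
  onsets <- integer(0)
  labels <- character(0)
  jitter_mag <- numeric(0)
  pos <- 0L
  i <- 0L
  repeat {
    period <- mean_period * (1 + rnorm_trunc(1, 0, 0.03))
    n <- as.integer(round(period * fs))
    if (pos + n > total) break
    i <- i + 1L

    rel <- rnorm(10, 0, spec$amplitude_jitter_cv / 100)
    a <- pmax(tpl$amplitudes * (1 + rel), 0)
    # beats are foot-aligned, so the fundamental's phase is anchored to the
    # onset; beat-to-beat phase scatter lives in the relative phases of
    # harmonics 2..10
    ph <- tpl$phases + c(0, rnorm(9, 0, spec$phase_jitter_sd))
    distorted <- runif(1) < spec$artifact_rate
    channel <- NA_character_
    if (distorted) {
      channel <- if (length(spec$artifact_model) == 1L) spec$artifact_model
                 else sample(spec$artifact_model, 1L)
      if (channel == "damping") {
        a[4:10] <- a[4:10] * runif(1, 0.2, 0.6)
        ph <- ph + c(0, rnorm(9, 0, 10))
      }
    }
    beat <- synth_core(tpl$dc_level, a, wrap_deg(ph), n)
    if (distorted && channel == "baseline_drift")
      beat <- artifact_drift(beat, fs, sum(tpl$amplitudes))
    if (distorted && channel == "spike")
      beat <- artifact_spike(beat, fs, a[1])

    samples[[i]] <- beat
    onsets <- c(onsets, pos + 1L)
    labels <- c(labels, if (distorted) "low" else "high")
    jitter_mag <- c(jitter_mag,
                    mean(abs(rel)[tpl$amplitudes > 0]))
    pos <- pos + n
  }
  if (i == 0L) stop("'duration' too short to hold a single beat")

  structure(list(subject_id = subject_id, regime = regime,
                 sampling_rate = fs,
                 samples = unlist(samples[seq_len(i)]),
                 truth_onsets = onsets,
                 truth_beat_labels = labels,
                 hr = hr, jitter_mag = jitter_mag),
            class = "pulse_record")
  })
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf("Pulse record: subject %s, %s contact pressure\n",
              x$subject_id, x$regime))
  cat(sprintf("  %d samples at %g Hz (%.1f s), %d beats",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              length(x$truth_onsets)))
  if (length(x$truth_beat_labels))
    cat(sprintf(", %.1f%% high quality",
                100 * mean(x$truth_beat_labels == "high")))
  cat("\n")
  invisible(x)
}

#' @export
plot.pulse_record <- function(x, seconds = 5, ...) {
  n <- min(length(x$samples), round(seconds * x$sampling_rate))
  t <- (seq_len(n) - 1) / x$sampling_rate
  plot(t, x$samples[seq_len(n)], type = "l",
       xlab = "time (s)", ylab = "pressure (a.u.)",
       main = sprintf("%s / %s pressure", x$subject_id, x$regime), ...)
  on <- x$truth_onsets[x$truth_onsets <= n]
  if (length(on)) abline(v = (on - 1) / x$sampling_rate, col = "grey70", lty = 3)
  invisible(x)
}

#' Simulate a full two-regime cohort
#'
#' Generates, for each subject, one recording under the appropriate contact
#' pressure and one under the higher contact pressure. The subject's heart
#' rate is drawn once and shared by both recordings, mirroring the paired
#' measurement protocol (1 min at appropriate pressure, rest, 1 min at
#' higher pressure). Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `pulse_cohort`: a list of
#'   `2 * n_subjects` [generate_record()] results (appropriate then higher
#'   per subject), with the configuration attached as attribute `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_subjects = 2, duration = 10, seed = 1))
#' length(cohort)  # 4 records
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
  n <- config$n_subjects
  hrs <- rnorm_trunc(n, config$hr_mean, config$hr_sd)
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * n), nrow = n)
  ids <- sprintf("s%02d", seq_len(n))
  records <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    records[[2L * i - 1L]] <- generate_record(config, ids[i], "appropriate",
                                              hr = hrs[i], seed = seeds[i, 1L])
    records[[2L * i]] <- generate_record(config, ids[i], "higher",
                                         hr = hrs[i], seed = seeds[i, 2L])
  }
  structure(records, class = "pulse_cohort", config = config)
  })
}

#' @export
print.pulse_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  nb <- vapply(x, function(r) length(r$truth_onsets), integer(1))
  cat(sprintf("Pulse cohort: %d records (%d subjects x 2 regimes), %d beats total\n",
              length(x), cfg$n_subjects, sum(nb)))
  for (rg in c("appropriate", "higher")) {
    sel <- vapply(x, function(r) r$regime == rg, logical(1))
    hq <- unlist(lapply(x[sel], function(r) r$truth_beat_labels)) == "high"
    cat(sprintf("  %-11s: %5d beats, %.1f%% high quality\n",
                rg, length(hq), 100 * mean(hq)))
  }
  invisible(x)
}
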
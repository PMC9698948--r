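#' Harmonic template of a single pulse
#'
#' A pulse beat is modelled as a truncated cosine series
#' \deqn{x(t) = dc + \sum_{n=1}^{10} a_n \cos(2\pi n t / T + \phi_n \pi/180)}
#' over one cardiac period \eqn{T}. A template stores the DC level, the ten
#' harmonic amplitudes \eqn{a_1..a_{10}} (arbitrary pressure units) and the
#' ten phase angles \eqn{\phi_1..\phi_{10}} in degrees, wrapped to
#' \eqn{(-180, 180]}.
#'
#' The default template has geometrically decaying amplitudes
#' (\eqn{a_n = 0.5^{n-1}}) and phase lags increasing linearly with harmonic
#' number around 180 degrees (\eqn{\phi_n = 182 - 0.7n}; the small offsets
#' from 180 centre the waveform's global minimum on the start of the
#' cycle). The synthesized beat therefore has its foot at the beat onset,
#' as a measured radial pulse does, with a mildly asymmetric systolic
#' upstroke.
#'
#' @param dc_level baseline pressure offset (arbitrary units).
#' @param amplitudes numeric vector of up to 10 non-negative harmonic
#'   amplitudes; padded with zeros to length 10.
#' @param phases numeric vector of phase angles in degrees, same length as
#'   `amplitudes`; wrapped into `(-180, 180]`.
#' @return An object of class `harmonic_template` with fields `dc_level`,
#'   `amplitudes` (length 10) and `phases` (length 10).
#' @seealso [synthesize_beat()], [decompose_beat()]
#' @export
#' @examples
#' tpl <- harmonic_template()
#' tpl$amplitudes
harmonic_template <- function(dc_level = 8,
                              amplitudes = 0.5^(0:9),
                              phases = 182 - 0.7 * (1:10)) {
  if (length(amplitudes) > 10L || length(phases) > 10L)
    stop("at most 10 harmonics are supported")
  if (length(amplitudes) != length(phases))
    stop("'amplitudes' and 'phases' must have the same length")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop("harmonic amplitudes must be finite and non-negative")
  a <- c(amplitudes, rep(0, 10L - length(amplitudes)))
  p <- wrap_deg(c(phases, rep(0, 10L - length(phases))))
  structure(list(dc_level = dc_level, amplitudes = a, phases = p),
            class = "harmonic_template")
}

#' @export
print.harmonic_template <- function(x, ...) {
  cat("Harmonic pulse template (10 harmonics)\n")
  cat("  dc level  :", format(x$dc_level), "\n")
  cat("  amplitudes:", paste(signif(x$amplitudes, 3), collapse = " "), "\n")
  cat("  phases    :", paste(signif(x$phases, 4), collapse = " "), "deg\n")
  invisible(x)
}

#' Contact-pressure regime specification
#'
#' Describes how beats are generated under one sensor contact-pressure
#' condition: the underlying harmonic template, the beat-to-beat jitter
#' applied to it, and the probability and type of motion-artifact
#' distortion. The two study conditions are `"appropriate"` (~68 mmHg
#' contact pressure, mostly clean beats) and `"higher"` (~152 mmHg, mostly
#' distorted beats); the pressures themselves are metadata and do not enter
#' the signal model.
#'
#' @param label `"appropriate"` or `"higher"`.
#' @param template a [harmonic_template()].
#' @param amplitude_jitter_cv per-harmonic multiplicative beat-to-beat
#'   coefficient of variation of the amplitudes, in percent.
#' @param phase_jitter_sd per-harmonic additive beat-to-beat standard
#'   deviation of the phases, in degrees.
#' @param artifact_rate probability in `[0, 1]` that a beat is distorted
#'   (labelled low quality).
#' @param artifact_model character vector drawn from
#'   `c("baseline_drift", "spike", "damping")`; a distorted beat picks one
#'   channel uniformly at random from this set.
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(label = c("appropriate", "higher"),
                        template = harmonic_template(),
                        amplitude_jitter_cv = if (label == "higher") 8 else 2,
                        phase_jitter_sd = if (label == "higher") 6 else 2,
                        artifact_rate = if (label == "higher") 0.782 else 0.02,
                        artifact_model = c("baseline_drift", "spike", "damping")) {
  label <- match.arg(label)
  artifact_model <- match.arg(artifact_model, several.ok = TRUE)
  stopifnot(inherits(template, "harmonic_template"))
  if (!is.numeric(artifact_rate) || artifact_rate < 0 || artifact_rate > 1)
    stop("'artifact_rate' must lie in [0, 1]")
  if (amplitude_jitter_cv < 0 || phase_jitter_sd < 0)
    stop("jitter parameters must be non-negative")
  structure(list(label = label, template = template,
                 amplitude_jitter_cv = amplitude_jitter_cv,
                 phase_jitter_sd = phase_jitter_sd,
                 artifact_rate = artifact_rate,
                 artifact_model = artifact_model),
            class = "regime_spec")
}

#' Simulation configuration for a two-regime tonometry cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort
#' size, heart-rate distribution, recording duration and sampling rate, the
#' two contact-pressure regimes, and the quality mixture — the fraction of
#' clean (high-quality) beats under the appropriate contact pressure and the
#' fraction of distorted (low-quality) beats under the higher contact
#' pressure. Defaults reproduce the reference cohort: 60 subjects, heart
#' rate 69.57 +/- 10.73 beats/min, 1-min recordings sampled at 1024 Hz,
#' 98.0% clean beats at appropriate pressure and 78.2% distorted beats at
#' higher pressure.
#'
#' The regimes' `artifact_rate`s are set from the two mixture fractions, so
#' the fractions are the single source of truth for the quality mixture.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param hr_mean,hr_sd population mean and SD of subject heart rate,
#'   beats/min.
#' @param duration recording duration per condition, seconds.
#' @param sampling_rate sampling rate, Hz. Must resolve the 10th harmonic of
#'   the fastest plausible heart rate.
#' @param regimes named list with elements `appropriate` and `higher`, each
#'   a [regime_spec()].
#' @param clean_fraction_appropriate fraction of clean beats under the
#'   appropriate contact pressure.
#' @param lowq_fraction_higher fraction of distorted beats under the higher
#'   contact pressure.
#' @param seed integer seed controlling all randomness downstream.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 4, seed = 7)
#' cfg$regimes$higher$artifact_rate
sim_config <- function(n_subjects = 60,
                       hr_mean = 69.57, hr_sd = 10.73,
                       duration = 60, sampling_rate = 1024,
                       regimes = list(appropriate = regime_spec("appropriate"),
                                      higher = regime_spec("higher")),
                       clean_fraction_appropriate = 0.980,
                       lowq_fraction_higher = 0.782,
                       seed = 1L) {
  if (n_subjects < 2) stop("'n_subjects' must be at least 2")
  if (clean_fraction_appropriate < 0 || clean_fraction_appropriate > 1 ||
      lowq_fraction_higher < 0 || lowq_fraction_higher > 1)
    stop("mixture fractions must lie in [0, 1]")
  if (duration <= 0) stop("'duration' must be positive")
  stopifnot(is.list(regimes),
            inherits(regimes$appropriate, "regime_spec"),
            inherits(regimes$higher, "regime_spec"))
  # Nyquist-type guard: the 10th harmonic of the fastest plausible beat
  # (mean HR + 3 SD) must be below half the sampling rate
  f_max <- (hr_mean + 3 * hr_sd) / 60
  if (sampling_rate < 2 * 10 * f_max)
    stop("'sampling_rate' too low to resolve 10 harmonics at this heart rate")
  regimes$appropriate$artifact_rate <- 1 - clean_fraction_appropriate
  regimes$higher$artifact_rate <- lowq_fraction_higher
  if (regimes$higher$amplitude_jitter_cv <= regimes$appropriate$amplitude_jitter_cv ||
      regimes$higher$phase_jitter_sd <= regimes$appropriate$phase_jitter_sd)
    warning("the 'higher' regime usually has strictly larger jitter than ",
            "the 'appropriate' regime; check the regime specs")
  structure(list(n_subjects = as.integer(n_subjects),
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 duration = duration, sampling_rate = sampling_rate,
                 regimes = regimes,
                 clean_fraction_appropriate = clean_fraction_appropriate,
                 lowq_fraction_higher = lowq_fraction_higher,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Tonometry cohort simulation config\n")
  cat(sprintf("  %d subjects, HR %.2f +/- %.2f bpm, %g s at %g Hz\n",
              x$n_subjects, x$hr_mean, x$hr_sd, x$duration, x$sampling_rate))
  cat(sprintf("  appropriate pressure: %.1f%% clean beats\n",
              100 * x$clean_fraction_appropriate))
  cat(sprintf("  higher pressure     : %.1f%% low-quality beats\n",
              100 * x$lowq_fraction_higher))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
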
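---
title: "Methods: simulating and screening radial pulse waveforms by quality"
author: "pulseqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and screening radial pulse waveforms by quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseqc)
```

## The problem

Radial blood-pressure waveforms (BPW) measured by skin-surface tonometry
are exquisitely sensitive to how hard the sensor is held against the
artery. At an appropriate contact pressure (around diastolic pressure,
~68 mmHg) almost every pulse is clean; when the sensor is strapped too
tightly (~152 mmHg) most pulses are distorted by motion artifacts and
vessel compression, and their spectral content becomes unstable from beat
to beat. `pulseqc` implements a beat-wise screening workflow for this
situation: simulate paired recordings under the two contact-pressure
regimes, segment them into beats, describe each beat by 40 Fourier
harmonic indices, and train classifiers that separate high- from
low-quality pulses.

## Signal model

A beat of period $T$ is a truncated cosine series

$$x(t) = dc + \sum_{n=1}^{10} a_n \cos\!\left(\frac{2\pi n t}{T} +
\frac{\pi \phi_n}{180}\right),$$

with amplitudes $a_n$ in arbitrary pressure units and phases $\phi_n$ in
degrees wrapped to $(-180, 180]$. Ten harmonics cover the clinically used
BPW band at physiological heart rates; the sampling-rate validator in
`sim_config()` enforces that the 10th harmonic of the fastest plausible
beat stays below Nyquist.

Beats are discretized as $N = \mathrm{round}(T f_s)$ samples uniformly
spaced over exactly one cycle. This grid convention is deliberate: the
discrete Fourier transform of one beat then has the beat's harmonics
exactly on bins $1..10$, so `decompose_beat()` (an FFT projection)
recovers a synthesized template to machine precision, and the round-trip
identity `decompose(synthesize(T)) = T` becomes a sharp regression test
rather than an approximation. The residual sampling-grid distortion in a
concatenated beat train is below half a sample per beat (< 0.05% of the
period at 1024 Hz).

### Default template

Subject-level harmonic content is configurable; the shipped default has
geometrically decaying amplitudes $a_n = 0.5^{\,n-1}$ (radial-pulse
spectra decay roughly geometrically, and only *relative* content matters
to every downstream index) and phase lags increasing linearly with
harmonic number near 180 degrees, $\phi_n = 182 - 0.7n$. Phases near 180
make every harmonic trough together at the beat boundary, so a
synthesized beat has its foot at the start of its cycle like a measured
pulse; the small linear offsets from 180 were chosen once, numerically,
so that the continuous waveform's global minimum falls on the boundary
to within a tenth of a sample. This matters because the segmentation
acceptance check compares detected feet against generator beat
boundaries with a ±10 ms gate.

### Beat-to-beat variability and the two regimes

Within a recording, per-beat periods are Gaussian around $60/\mathrm{HR}$
with CV 3% (truncated at ±3 SD; physiologic sinus variability, keeps
periods positive). Each beat's template is jittered:

* amplitudes: multiplicative Gaussian noise with per-regime CV
  (default 2% appropriate, 8% higher);
* phases: additive Gaussian noise with per-regime SD (default 2°
  appropriate, 6° higher) applied to harmonics 2–10 only. The
  fundamental's phase is anchored to the onset because beats are
  foot-aligned by construction: jittering $\phi_1$ would slide the
  waveform's foot off the beat boundary, which is an artifact of
  parametrization, not physiology. A side effect worth knowing: for
  clean beats $P_1$ is constant within a record and $P_1{\_}SD$ is
  exactly zero, so group differences concentrate in $n \ge 2$ — the same
  pattern reported for measured data, where $P_1$ shows no significant
  contact-pressure effect.

Each beat is independently distorted with the regime's artifact rate.
The rates are derived from the two study mixture fractions: 98.0% clean
beats at appropriate pressure and 78.2% distorted beats at higher
pressure, which the simulator treats as per-beat Bernoulli
probabilities, so realized fractions concentrate binomially. Three
distortion channels are implemented (tonometry artifact waveforms are
not standardized, so these are the package's own parameterized choices,
drawn uniformly per distorted beat):

* `baseline_drift`: an additive 0.3–0.8 Hz sinusoid at 20–50% of the
  total harmonic amplitude — slow probe-pressure wander;
* `spike`: a ±(0.5–1.5)·$a_1$ Gaussian transient 10–30 ms wide — a
  motion bump;
* `damping`: harmonics 4–10 attenuated to 20–60% with extra 10° phase
  scatter (harmonics 2–10) — partial vessel occlusion smoothing the
  waveform.

All three inflate the beat-to-beat variability indices ($CV_n$,
$P_n{\_}SD$) and perturb per-beat $C_n$/$P_n$, reproducing the
qualitative group signature of over-pressured recordings. The contact
pressures themselves (67.80 and 151.80 mmHg) are carried as regime
metadata only.

### What the generator does not emulate

No pressure–flow (Windkessel) dynamics, no respiratory modulation, no
baseline wander on *clean* beats, no sensor quantization, no ectopy, and
subject templates differ only through jitter realizations, not through
systematic inter-subject spectral differences. Consequently the
classification task is easier than on measured data: classifiers reach
near-perfect discrimination on the default cohort, and passing tests
demonstrate the correctness and leakage-freedom of the harness, not the
clinical difficulty of the problem. The headline real-data figure of the
motivating study (random-forest leave-one-subject-out AUC 0.96) is not
reproducible without that study's recordings; the corresponding check
here is a lower bound (median AUC ≥ 0.90 over ten simulated cohorts)
plus a permutation null.

## Segmentation

`detect_beat_onsets()` is a slope-threshold foot detector: the 5
ms-smoothed derivative is thresholded at $k \times$ its median absolute
deviation ($k = 2$), suprathreshold upstrokes are merged within a
refractory period of $60/\mathrm{HR_{max}}$ s, upstrokes whose peak
slope is under half the record's median peak slope are rejected
(suppressing detections on diastolic oscillations), and each remaining
upstroke is traced back (≤ 0.25 s) to the preceding local minimum — the
pulse foot. On a flat plateau the *last* minimal sample before the
upstroke is taken, so a beat sitting on a constant diastolic baseline is
dated at the upstroke side of the plateau. Flat or featureless signals
return zero onsets with a warning rather than an error, since an
upstream acquisition failure is data, not a programming fault; when the
derivative spread is exactly zero but a slope exists, the threshold
falls back to half the peak slope (the single-beat-on-baseline case).

`segment_beats()` forms half-open segments between consecutive onsets
(1-based, in the R convention; on-disk interchange files are 0-based),
discards the partial first/last beats, and gates periods to 0.25–2.0 s
(heart rates 30–240 beats/min). Gated-out beats are counted and
reported, never silently imputed.

## The 40 harmonic indices

Per beat, `build_feature_table()` derives:

* $C_n$: amplitude proportions $a_n / \sum_{k=1}^{10} a_k$. The
  "proportion of total harmonic amplitude" denominator is the default
  because proportions of a whole sum to one; normalization by $a_1$ is
  available (`normalization = "fundamental"`) for comparability with
  conventions that express harmonics relative to the fundamental.
* $P_n$: phase angles in degrees, cosine convention, beat-onset time
  origin, wrapped to $(-180, 180]$. Degrees were chosen as the unit
  throughout. The phase of a numerically zero harmonic is undefined and
  propagates as a dropped beat rather than an imputed value.
* $CV_n = 100\,\mathrm{SD}(C_n)/\mathrm{mean}(C_n)$ and
  $P_n{\_}SD = \mathrm{SD}(P_n)$, computed over a window of beats with
  the sample ($n-1$) denominator. Phase sequences are unwrapped before
  the SD so that values straddling the ±180° seam do not inflate it.
  Variability needs several beats while the feature rows are per beat;
  the default window is the whole record (every beat of a record shares
  the record-level statistic), the simplest reading consistent with
  beat-level rows, with a centred sliding window (`window = w`)
  available for sub-minute locality.

Beats with any undefined feature are dropped and counted. The invariants
$\sum_n C_n = 1$, $CV_n \ge 0$, $P_n{\_}SD \ge 0$, and invariance of
$C_n$/$P_n$ under positive rescaling of the signal are enforced by
tests.

## Classifier evaluation

Training pools emulate the expert-curated sets: high-quality beats of
appropriate-pressure recordings versus low-quality beats of
higher-pressure recordings (`select_quality_beats()`); "high quality" is
the positive class. Eight methods run with fixed, documented defaults
(SVM with RBF kernel and cost 1; MLP with one hidden layer of 32 units,
at most 500 iterations; Gaussian naive Bayes; a fully grown decision
tree; random forest with 100 trees; logistic regression; LDA; KNN with
k = 5) — the motivating study names the methods but no hyperparameters,
so reproducible defaults were fixed rather than guessed at, and all are
overridable. Features are standardized with training-portion statistics
only; the leave-one-subject-out loop asserts by subject-id bookkeeping
that no held-out row (including accidental duplicates) enters the pool.

Three protocols:

* **Threefold CV**, stratified by class at the beat level (the reference
  analysis pools beats across subjects; subject-grouped folds are
  offered via `group_by_subject = TRUE` for the stricter reading).
* **Leave-one-subject-out.** Each held-out *recording* receives one
  label by majority vote over its beat predictions, ties resolved toward
  low quality (the conservative direction for a quality screen);
  recording truth is the pressure condition; the AUC uses the
  recording-level fractions of beats predicted high-quality. The
  reference table's counts sum to 60 units for 60 subjects with two
  recordings each, which cannot be reconstructed from the text; this
  package reports all `2 x n_subjects` recordings, with beat-level
  counting available (`unit = "beat"`).
* **Hold-out 8:2**, split by subject (never by beat), threefold CV on
  the training portion plus one final hold-out row.

Seed-taking functions evaluate under the given seed and then restore the
caller's RNG stream, so embedding them in Monte-Carlo loops (e.g.
permutation nulls) does not silently freeze the outer randomness.

The permutation null for the leave-one-subject-out AUC shuffles the
recording truth labels against the fitted recording scores. Retraining a
fully grown forest on beat-label noise is not used as the null: besides
being two orders of magnitude slower, majority voting under a non-50%
base rate interacts with the regimes' different feature-space densities
and biases that statistic away from 0.5 even when no label information
is present — the score-versus-shuffled-truth permutation is the exact
null for the rank statistic being tested.

## Numerical choices and degenerate inputs

* Phase wrap is $(-180, 180]$; $-180$ maps to $+180$.
* Zero-variance groups with equal means compare at $p = 1$ (no flag);
  significance flags are `*` for $p < 0.05$ and `+` for
  $0.05 < p < 0.1$. Welch's unequal-variance test is the default — the
  group test in the motivating study is unnamed — with a paired variant
  available since both pressures were measured on the same subjects.
  `compare_indices()` collapses to one value per recording by default to
  avoid pseudo-replication from record-level features; beat pooling is
  available.
* Confusion-matrix metrics are kept at full precision and rounded to two
  decimals only for display; undefined ratios surface as `NA`.
* Probability ties at 0.5 classify as low quality, consistently with the
  majority-vote tie-break.
* A cohort too small for a protocol warns (2 subjects) or errors (a
  class missing from a fold) rather than returning silently unstable
  numbers.

## Problem sizes used in the tests

Unit tests run on scaled-down cohorts (3–4 subjects, 20–30 s records)
chosen to exercise every code path with a few hundred beats; the
whole-pipeline checks use the full default conditions — 60 subjects,
1-min paired recordings at 1024 Hz (~8,000 beats), 150 subjects
(~20,000 beats) for the mixture-calibration check, ten independent
60-subject cohorts for the leave-one-subject-out summary. These sizes
are the package's chosen trade-off between binomial/Monte-Carlo
tolerance and a test suite that runs in minutes.

## Known limitations

* The synthetic cohort is easier to classify than measured data (see
  above); absolute performance numbers on it are upper bounds.
* The foot detector is designed for the simulated waveform family
  (clean feet, moderate drift); it is not a general-purpose arterial
  onset detector and is not ECG-referenced.
* $CV_n$ and $P_n{\_}SD$ with the default whole-record window make
  record identity partially recoverable from features; protocols that
  must exclude subject leakage should use subject-grouped folds, as the
  leave-one-subject-out protocol does by construction.
* No multiple-testing correction is applied to the 40 group comparisons,
  matching the reference analysis; interpret individual flags
  accordingly.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 6, duration = 30, seed = 7)
cohort <- generate_cohort(cfg)
features <- build_feature_table(cohort)
eval_loso <- quality_eval(features, protocol = "loso", methods = c("RF", "LDA"),
                          seed = 7)
eval_loso
compare_indices(features, by = "regime")[11:20, c("index", "mean_a", "mean_b",
                                                  "p_value", "flag")]
```
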
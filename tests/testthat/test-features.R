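test_that("decompose_beat recovers trivial beats", {
  x <- cos(2 * pi * (0:879) / 880)
  dec <- decompose_beat(x)
  expect_equal(dec$amplitudes[1], 1, tolerance = 1e-6)
  expect_lt(abs(dec$phases[1]), 1e-4)
  expect_true(all(dec$amplitudes[2:10] < 1e-6))

  const <- decompose_beat(rep(3.7, 100))
  expect_equal(const$dc, 3.7, tolerance = 1e-12)
  expect_true(all(const$amplitudes < 1e-9))

  expect_error(decompose_beat(rnorm(15)), "too short")
})

test_that("synthesize/decompose round-trips random templates", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(10, 0.05, 2)
    ph <- runif(10, -179, 180)
    tpl <- harmonic_template(dc_level = runif(1, -2, 10),
                             amplitudes = a, phases = ph)
    period <- runif(1, 0.25, 2)
    dec <- decompose_beat(synthesize_beat(tpl, period, 1024))
    expect_equal(dec$dc, tpl$dc_level, tolerance = 1e-6)
    expect_equal(dec$amplitudes, tpl$amplitudes, tolerance = 1e-6)
    expect_true(all(abs(wrap_deg_diff(dec$phases, tpl$phases)) < 1e-3))
  }
})

test_that("ten harmonics explain a synthetic beat almost completely", {
  tpl <- harmonic_template()
  x <- synthesize_beat(tpl, 0.9, 1024)
  dec <- decompose_beat(x)
  recon <- pulseqc:::synth_core(dec$dc, dec$amplitudes, dec$phases, length(x))
  expect_gt(1 - var(x - recon) / var(x), 0.999)
})

test_that("amplitude proportions normalize and fail on zero content", {
  d <- structure(list(dc = 0, amplitudes = c(1, 1, rep(0, 8)),
                      phases = rep(0, 10)), class = "harmonic_decomposition")
  expect_equal(amplitude_proportions(d), c(0.5, 0.5, rep(0, 8)))

  d$amplitudes <- c(2, 1, 1, rep(0, 7))
  expect_equal(amplitude_proportions(d), c(0.5, 0.25, 0.25, rep(0, 7)))
  expect_equal(amplitude_proportions(d, "fundamental"),
               c(1, 0.5, 0.5, rep(0, 7)))

  # default template: proportions equal amplitudes over their sum
  tpl <- harmonic_template()
  dec <- decompose_beat(synthesize_beat(tpl, 0.8, 1024))
  expect_equal(amplitude_proportions(dec),
               tpl$amplitudes / sum(tpl$amplitudes), tolerance = 1e-9)

  d$amplitudes <- rep(0, 10)
  expect_error(amplitude_proportions(d), "zero harmonic content")
})

test_that("phase angles wrap, flag zero harmonics, and obey the shift theorem", {
  tpl <- harmonic_template(dc_level = 0, amplitudes = c(1, 0.4, 0.3),
                           phases = c(10, -40, 60))
  x <- synthesize_beat(tpl, 1, 1024)
  p <- phase_angles(decompose_beat(x))
  expect_equal(p[3], 60, tolerance = 1e-3)
  expect_true(all(is.na(p[4:10])))

  # wrapping convention: 180 + eps lands just above -180
  expect_equal(pulseqc:::wrap_deg(180.5), -179.5)
  expect_equal(pulseqc:::wrap_deg(180), 180)
  expect_equal(pulseqc:::wrap_deg(-180), 180)

  # circular shift by delta samples shifts P_n by -n*360*delta/N
  n <- length(x)
  for (delta in c(17, 150)) {
    shifted <- c(x[(delta + 1):n], x[1:delta])
    ps <- phase_angles(decompose_beat(shifted))
    expected <- pulseqc:::wrap_deg(p[1:3] - (1:3) * 360 * (-delta) / n)
    expect_true(all(abs(wrap_deg_diff(ps[1:3], expected)) < 1e-6))
  }
})

test_that("scale invariance: C_n and P_n unchanged by positive rescaling", {
  x <- synthesize_beat(harmonic_template(), 0.7, 1024)
  d1 <- decompose_beat(x)
  d2 <- decompose_beat(3.5 * x)
  expect_equal(amplitude_proportions(d1), amplitude_proportions(d2),
               tolerance = 1e-12)
  expect_equal(phase_angles(d1), phase_angles(d2), tolerance = 1e-9)
})

test_that("windowed variability matches hand computations", {
  s <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(windowed_variability(s, "record", "cv")[, 1],
               rep(50, 3))  # mean 2, sample SD 1
  expect_equal(windowed_variability(matrix(5, 4, 1), "record", "cv")[, 1],
               rep(0, 4))
  expect_equal(windowed_variability(matrix(30, 5, 1), "record", "sd")[, 1],
               rep(0, 5))

  # phase SD is seam-free: values straddling +/-180 have small spread
  p <- matrix(c(179, -179, 178, -178), 4, 1)
  expect_lt(windowed_variability(p, "record", "sd")[1, 1], 3)

  # sliding window differs from the record-level statistic
  s2 <- matrix(c(1, 1, 1, 9, 9, 9), 6, 1)
  sw <- windowed_variability(s2, 3, "cv")
  expect_equal(sw[1, 1], 0)
  expect_gt(sw[4, 1], 0)

  expect_error(windowed_variability(matrix(1, 1, 1), "record", "cv"),
               "at least 2 beats")
})

test_that("the feature table has the documented schema and invariants", {
  ft <- test_features()
  expect_s3_class(ft, "pulse_features")
  expect_equal(ncol(ft), 44)
  expect_named(ft, c("subject", "regime", "beat_index", "label",
                     pulseqc:::feature_names()))
  expect_true(all(abs(rowSums(ft[, paste0("C", 1:10)]) - 1) < 1e-9))
  expect_true(all(ft[, paste0("CV", 1:10)] >= 0))
  expect_true(all(ft[, paste0("P", 1:10, "_SD")] >= 0))
  expect_true(all(ft$label %in% c("high", "low")))
})

test_that("the higher-pressure regime inflates CV_n and P_n_SD", {
  ft <- test_features()
  for (set in list(paste0("CV", 1:10), paste0("P", 1:10, "_SD"))) {
    m_app <- colMeans(ft[ft$regime == "appropriate", set])
    m_hi <- colMeans(ft[ft$regime == "higher", set])
    expect_true(all(m_hi > m_app))
  }
})
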
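test_that("synthesize_beat reproduces single-harmonic and constant cases", {
  tpl <- harmonic_template(dc_level = 0, amplitudes = 1, phases = 0)
  x <- synthesize_beat(tpl, period = 1, sampling_rate = 1024)
  expect_length(x, 1024)
  expect_equal(x[1], 1.0)
  expect_equal(x, cos(2 * pi * (0:1023) / 1024), tolerance = 1e-12)

  flat <- harmonic_template(dc_level = 5, amplitudes = rep(0, 10),
                            phases = rep(0, 10))
  expect_equal(synthesize_beat(flat, 0.8, 1024),
               rep(5, round(0.8 * 1024)))
})

test_that("synthesize_beat matches independent pointwise evaluation", {
  tpl <- harmonic_template(dc_level = 0, amplitudes = c(1.0, 0.5, 0.2),
                           phases = c(0, 30, 60))
  for (period in c(0.5, 0.83, 1.7)) {
    x <- synthesize_beat(tpl, period, 1024)
    n <- round(period * 1024)
    expect_equal(x, oracle_cosine_series(0, c(1, 0.5, 0.2), c(0, 30, 60), n),
                 tolerance = 1e-9)
  }
})

test_that("synthesize_beat rejects invalid arguments", {
  tpl <- harmonic_template()
  expect_error(synthesize_beat(tpl, period = 0, sampling_rate = 1024),
               "positive")
  expect_error(synthesize_beat(tpl, period = -1, sampling_rate = 1024),
               "positive")
  expect_error(synthesize_beat(tpl, period = 0.01, sampling_rate = 1024),
               "21 samples")
})

test_that("generate_record is reproducible and beat counts track heart rate", {
  cfg <- sim_config(n_subjects = 2, duration = 60, seed = 5)
  r1 <- generate_record(cfg, "sA", "appropriate", hr = 60, seed = 99)
  r2 <- generate_record(cfg, "sA", "appropriate", hr = 60, seed = 99)
  expect_identical(r1, r2)

  nb <- length(r1$truth_onsets)
  expect_true(abs(nb - 60) <= 2)
  expect_true(all(diff(r1$truth_onsets) > 0))
  expect_length(r1$truth_beat_labels, nb)
  expect_true(all(r1$truth_onsets <= length(r1$samples)))

  expect_error(generate_record(sim_config(n_subjects = 2, duration = 0.3),
                               "sA", "appropriate", hr = 60, seed = 1),
               "duration")
})

test_that("realized quality mixture concentrates on the configured fractions", {
  # ~2600 beats per regime: binomial 3 SE bands around 0.980 / 0.782
  cfg <- sim_config(n_subjects = 40, duration = 60, seed = 77)
  co <- generate_cohort(cfg)
  lab <- function(rg) unlist(lapply(
    co[vapply(co, function(r) r$regime == rg, logical(1))],
    function(r) r$truth_beat_labels))
  la <- lab("appropriate")
  lh <- lab("higher")
  se_a <- sqrt(0.98 * 0.02 / length(la))
  se_h <- sqrt(0.782 * 0.218 / length(lh))
  expect_true(abs(mean(la == "high") - 0.980) < 3 * se_a)
  expect_true(abs(mean(lh == "low") - 0.782) < 3 * se_h)
})

test_that("cohorts share heart rate within subject and have paired records", {
  co <- generate_cohort(sim_config(n_subjects = 2, duration = 20, seed = 9))
  expect_length(co, 4)
  ids <- vapply(co, `[[`, character(1), "subject_id")
  expect_equal(sort(unique(ids)), c("s01", "s02"))
  expect_equal(unname(table(ids)), c(2L, 2L), ignore_attr = TRUE)

  co2 <- generate_cohort(sim_config(n_subjects = 2, duration = 20, seed = 9))
  expect_identical(co, co2)

  # shared HR: mean beat period differs by < 10% between a subject's records
  for (s in c("s01", "s02")) {
    recs <- co[ids == s]
    mp <- vapply(recs, function(r) mean(diff(r$truth_onsets)) / r$sampling_rate,
                 numeric(1))
    expect_lt(abs(mp[1] - mp[2]) / mp[1], 0.10)
  }
})

test_that("the higher regime applies strictly larger amplitude jitter", {
  co <- test_cohort()
  jm <- function(rg) mean(unlist(lapply(
    co[vapply(co, function(r) r$regime == rg, logical(1))],
    function(r) r$jitter_mag)))
  expect_gt(jm("higher"), jm("appropriate"))
})
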
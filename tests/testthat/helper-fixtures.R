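# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small two-regime cohort under the default study conditions (scaled down)
test_cohort <- function() {
  fixture("cohort", function() {
    generate_cohort(sim_config(n_subjects = 4, duration = 30, seed = 101))
  })
}

test_features <- function() {
  fixture("features", function() {
    suppressMessages(build_feature_table(test_cohort()))
  })
}

# artifact-free cohort: clean beats only, for segmentation ground truth
test_clean_cohort <- function() {
  fixture("clean_cohort", function() {
    generate_cohort(sim_config(n_subjects = 3, duration = 30, seed = 202,
                               clean_fraction_appropriate = 1,
                               lowq_fraction_higher = 0))
  })
}

# synthetic linearly separable two-blob feature table (not from waveforms):
# blob geometry exercises the classifier harness independently of the
# harmonic pipeline
blob_features <- function(n_per_class = 120, sep = 4, n_subjects = 8,
                          seed = 303) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * 40), n, 40)
  lab <- rep(c("high", "low"), each = n_per_class)
  x[lab == "low", 1:10] <- x[lab == "low", 1:10] + sep
  colnames(x) <- pulseqc:::feature_names()
  subj <- sprintf("s%02d", rep_len(seq_len(n_subjects), n))
  regime <- ifelse(lab == "high", "appropriate", "higher")
  structure(data.frame(subject = subj, regime = regime,
                       beat_index = seq_len(n), label = lab, x,
                       stringsAsFactors = FALSE),
            class = c("pulse_features", "data.frame"))
}

# direct pointwise evaluation of the cosine series: the independent oracle
# for synthesize_beat
oracle_cosine_series <- function(dc, amplitudes, phases_deg, n) {
  vapply(0:(n - 1), function(k) {
    s <- dc
    for (h in seq_along(amplitudes))
      s <- s + amplitudes[h] * cos(2 * pi * h * k / n + phases_deg[h] * pi / 180)
    s
  }, numeric(1))
}

# full-size cohort under the default study conditions (60 subjects,
# 1-min recordings), shared by the acceptance checks
default_cohort_features <- function() {
  fixture("default_features", function() {
    suppressMessages(build_feature_table(generate_cohort(sim_config(seed = 1))))
  })
}

# signed angular difference a - b wrapped into (-180, 180]
wrap_deg_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# brute-force AUC by exhaustive pair counting (ties count one half)
oracle_auc <- function(scores, labels, positive = "high") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}
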
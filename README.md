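# pulseqc

Beat-to-beat quality assessment of radial blood-pressure waveforms (BPW)
measured by skin-surface tonometry.

## The problem

Wearable tonometry presses a pressure sensor against the skin over the
radial artery. The sensor's contact pressure decides everything: held at
an appropriate pressure (~68 mmHg) nearly every recorded pulse is clean,
while an over-tight strap (~152 mmHg) compresses the vessel and lets
motion artifacts through, distorting most pulses. Because artifact
spectra overlap the pulse band, contaminated beats cannot be filtered
out — they must be *identified* and discarded. `pulseqc` implements a
complete screening workflow for this task:

1. **Simulate** paired 1-min recordings per subject under the two
   contact-pressure regimes, with ground-truth beat boundaries and
   quality labels (98.0% clean beats at appropriate pressure, 78.2%
   distorted beats at higher pressure; 60 subjects with heart rate
   69.57 ± 10.73 beats/min at 1024 Hz by default).
2. **Segment** recordings into single beats by slope-threshold pulse-foot
   detection.
3. **Featurize** each beat by 40 Fourier harmonic indices, for harmonics
   $n = 1..10$ of the beat period: amplitude proportions
   $C_n = a_n / \sum_k a_k$, their beat-to-beat coefficients of variation
   $CV_n$ (%), phase angles $P_n$ (degrees), and phase standard
   deviations $P_n\_SD$ (degrees).
4. **Classify** high- versus low-quality pulses with eight supervised
   methods (SVM, MLP, Gaussian naive Bayes, decision tree, random
   forest, logistic regression, LDA, KNN) under three protocols:
   threefold cross-validation, leave-one-subject-out testing, and a
   subject-grouped 8:2 hold-out.
5. **Compare** every index between regimes (Welch tests with `*`/`+`
   significance flags) and summarize classifier performance by confusion
   matrices, accuracy, sensitivity, specificity and ROC AUC.

It is aimed at researchers developing signal-quality screens for
wearable pulse sensors who need a controlled, fully labelled test bed
and a leakage-free evaluation harness.

## Quick start

```r
library(pulseqc)

cfg <- sim_config(n_subjects = 6, duration = 30, seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> Pulse cohort: 12 records (6 subjects x 2 regimes), 390 beats total
#>   appropriate:   195 beats, 98.5% high quality
#>   higher     :   195 beats, 20.5% high quality

features <- build_feature_table(cohort)
ev <- quality_eval(features, protocol = "loso", methods = c("RF", "LDA"),
                   seed = 7)
ev
#> Leave-one-subject-out test (12 recordings)
#>    RF LDA
#> TP  6   6
#> FN  0   0
#> TN  6   6
#> FP  0   0
#>                  RF LDA
#> Sensitivity (%) 100 100
#> Specificity (%) 100 100
#> Accuracy (%)    100 100
#> AUC of ROC        1   1
```

Each held-out recording is labelled by majority vote over its beat
predictions; on this synthetic mini-cohort the regimes separate
perfectly (the simulation is an easier task than measured data — see the
methods vignette). The index-level group comparison mirrors the
regime effect:

```r
cmp <- compare_indices(features, by = "regime")
head(cmp[cmp$index %in% paste0("CV", 1:10),
         c("index", "mean_a", "mean_b", "p_value", "flag")])
#>    index   mean_a    mean_b      p_value flag
#> 11   CV1 1.590217  9.962182 1.502383e-06    *
#> 12   CV2 1.822782 13.154228 2.411392e-04    *
#> 13   CV3 4.195720 15.623514 2.370186e-03    *
#> 14   CV4 5.789197 38.010729 1.449042e-05    *
#> 15   CV5 7.652298 47.619715 1.054472e-06    *
#> 16   CV6 6.704688 55.532970 2.604600e-07    *
```

`mean_a` is the appropriate-pressure group, `mean_b` the
higher-pressure group: beat-to-beat harmonic variability is an order of
magnitude larger under excessive contact pressure, which is exactly the
signal the classifiers exploit.

Lower-level entry points: `synthesize_beat()` / `decompose_beat()` for
the harmonic model, `detect_beat_onsets()` / `segment_beats()` for
segmentation, `train_eval_threefold()`, `leave_one_subject_out()`,
`holdout_eval()` for individual protocols, `run_pipeline()` for the
whole chain with files on disk, and `write_record()` /
`read_waveform_csv()` for CSV + JSON-sidecar interchange.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "pulseqc",
                               load_package = "installed")'
```

## Documentation

The methods vignette (`vignettes/pulse-quality-methods.Rmd`) documents
the signal model, the artifact channels, the index definitions and
conventions, the evaluation protocols, and the package's numerical and
design choices in detail.
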
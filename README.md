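# wearsynth

Privacy-preserving synthesis of multimodal smartwatch sensor data for
wearable stress detection, in pure R.

Wrist-worn devices record six channels relevant to stress — three-axis
acceleration (ACC), blood volume pulse (BVP), electrodermal activity (EDA)
and skin temperature (TEMP) — but real stress datasets are small (typically
15 subjects, ~36 min each, ~30% stress by time) and privacy-sensitive.
`wearsynth` addresses both constraints for researchers in digital health and
privacy-preserving machine learning:

* a **conditional GAN** over labeled 60-s, six-channel signal windows
  (LSTM generator and discriminator, per-timestep label conditioning, and a
  diversity-sensitive regularizer `−λ · min(τ, ‖w₁−w₂‖/‖z₁−z₂‖)` with
  λ = 8, τ = 1 that discourages mode collapse), fitted with `cgan()` and
  sampled with `synthesize_subjects()` / `simulate()`;
* a **DP-CGAN**: the same architecture where only the discriminator trains
  under DP-SGD mechanics — per-example gradient clipping at C = 1.0,
  Gaussian noise with multiplier σ calibrated by a Rényi-DP accountant so
  that the full run spends at most ε ∈ {10, 1, 0.1} at δ = 10⁻³ (the
  generator, which never touches real data, keeps its ordinary optimizer);
* the surrounding pipeline: a seeded E4-like **synthetic cohort generator**,
  preparation (Fourier-method resampling to 1 Hz, neutral+amusement →
  non-stress relabeling, [0,1] min–max normalization, 60-s windows every
  30 or 60 s with majority-vote labels), a **quality suite** (classifier
  two-sample test, Pearson correlations with p-values, PCA/t-SNE
  embeddings, density comparisons), **FFT spectral featurization** (6×210
  averaged subwindow spectra), **CNN / CNN-LSTM / transformer stress
  classifiers**, and a **leave-one-subject-out harness** with ORIG / TSTR
  (train-synthetic-test-real) / AUGM (augmentation) strategies and a
  logistic-regression baseline sweep over all 63 channel subsets.

All network training runs on a small reverse-mode autodiff engine included
in the package; no deep-learning framework is required.

## Worked example

```r
library(wearsynth)

spec   <- fixture_spec(seed = 7)                      # 36-min sessions, 30% stress
cohort <- generate_cohort(spec, n_subjects = 4)
prep   <- prepare_cohort(cohort, stride_s = 30)
prep$windows
#> <window_set> 284 windows (60 s x 6 channels), stride 30 s
#>   subjects: 4 | stress share: 31.0%

rep <- correlation_with_p(prep$windows)
rep$r["EDA", "Label"]; rep$r["TEMP", "Label"]
#> r(EDA, label) = 0.865, r(TEMP, label) = -0.877
```

The prepared windows carry the expected stress physiology: EDA correlates
positively with the stress label, TEMP negatively. A (deliberately tiny)
GAN fit and a synthetic cohort:

```r
fit <- cgan(prep$windows,
            gan_config(epochs = 12, g_width = 16, d_widths = c(16, 8),
                       noise_dim = 8, batch_size = 32, seed = 2))
fit
#> <cgan> non-private, 12 epochs trained, widths G=16 D=16/8
#>   final losses: D=0.6403 G=0.4336

syn <- synthesize_subjects(fit, n_subjects = 3, seed = 5)
syn
#> <window_set> 108 windows (60 s x 6 channels), stride 60 s
#>   subjects: 3 | stress share: 30.6%

c2st(prep$windows, syn, seed = 1)
#> <c2st> accuracy both=1.000 stress=1.000 non-stress=1.000 (train 108 / test 108)
```

Each synthetic subject is 36 one-minute windows with exactly 11 stress
windows (30.6%, the study's class balance). After 12 epochs the classifier
two-sample test still separates real from synthetic perfectly (accuracy 1.0
— an untrained-quality generator); accuracy falling toward 0.5 with longer
training is the indistinguishability goal. A private training
specification:

```r
privacy_spec(epsilon = 10)
#> <privacy_spec> epsilon=10 delta=1.0e-03 C=1.00 sigma=1.789 (n=496, batch=8, accounted epochs=840)
```

σ = 1.789 is the smallest noise multiplier whose accounted spend over the
full run (n = 496 unique windows, batch 8, 2 × 420 accounted epochs for the
30-s sliding duplication) stays within ε = 10; pass it as
`gan_config(privacy = ...)` to train the DP-CGAN, or as
`classifier_config(privacy = ...)` for private classifier training. Full
LOSO experiments run through `experiment_plan()` / `run_experiment()`.

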
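---
title: "Privacy-preserving synthesis of wearable stress signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving synthesis of wearable stress signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wearsynth` generates, evaluates and consumes synthetic multimodal smartwatch
data for binary stress detection. This vignette is the package's account of
the science: the models, their assumptions, the tunable parameters, and the
design choices made where the design was genuinely open.

## The problem

Wrist-worn devices such as the Empatica E4 record six channels relevant to
stress: three-axis acceleration (ACC), blood volume pulse (BVP),
electrodermal activity (EDA) and skin temperature (TEMP), at heterogeneous
native rates (here 32, 64, 4 and 4 Hz). Stress physiology gives the signals
a directional structure: EDA rises under stress, TEMP falls, and the BVP
oscillation (a heart-rate proxy) speeds up. Real stress datasets are small
(a typical laboratory cohort is 15 subjects of ~36 minutes each, roughly 30%
stress / 70% non-stress by time) and privacy-sensitive, which motivates two
linked tools: a conditional GAN that synthesizes labeled signal windows, and
a differentially private variant whose outputs carry a formal (ε, δ)
guarantee.

## Synthetic cohort generator

`fixture_spec()` / `generate_cohort()` produce seeded cohorts with the
statistical structure above so every downstream stage is testable without
the real dataset. The signal model is deliberately simple: per-channel
baseline + label-dependent shift + AR(1)-smoothed noise, with BVP a
sinusoid whose frequency switches between a non-stress and a stress value.
Stress seconds form 2–4 contiguous blocks (laboratory protocols use block
designs) whose lengths are drawn randomly under the stress-fraction budget,
and 10% of non-stress seconds carry a distinct "amusement" code so that the
3-state→binary relabeling step is exercised nontrivially.

Default effect sizes were chosen once as physiologically plausible
magnitudes: EDA baseline ≈ 2 µS with inter-subject spread 0.5 µS and a +4 µS
stress shift; TEMP baseline ≈ 33.5 °C with a −1 °C shift; BVP at 1.1 Hz
(non-stress) vs 1.6 Hz (stress); AR(1) noise with lag-1 coefficient 0.95.
What the generator does **not** emulate: motion artifacts, non-stationary
drift, realistic cardiovascular waveform shape, or label noise. Passing
tests on these fixtures therefore demonstrate that the pipeline's operators
and contracts are correct — not that the GAN reproduces real physiology.

A consequence worth noting: after resampling to 1 Hz (Nyquist 0.5 Hz) the
1.1/1.6 Hz BVP oscillation is out of band, so BVP carries almost no label
information downstream — matching the weak BVP–label correlation typically
reported for real wrist data.

## Preparation pipeline

Four steps, mirroring common practice for this task:

1. **Resample to 1 Hz** with the Fourier method: truncate the DFT to the new
   bandwidth and inverse-transform (`resample_to_1hz()`). This aligns all
   channels on the label track's per-second grid and smooths
   high-frequency detail.
2. **Merge labels**: stress stays 1; neutral and amusement map to
   non-stress 0 (`merge_labels()`).
3. **Min–max normalize** each channel to [0, 1] (`minmax_normalize()`).
   The normalization scope is a genuine design choice: statistics are
   computed over the training sessions of the current cross-validation fold
   and *applied* (with clipping) to the held-out subject, avoiding test
   leakage. A constant channel maps to zero to avoid division by zero.
4. **Slice windows**: 60-s windows every `stride` seconds (30 or 60),
   0-based half-open intervals, trailing partial window dropped, so
   `floor((T−60)/stride)+1` windows. The window label is the majority of
   its 60 second-labels; a 30/30 tie is assigned to stress (favoring
   detector sensitivity; configurable).

## Conditional GAN

`cgan()` fits a conditional GAN over labeled 60×6 windows and returns an S3
object with `print`, `summary`, `plot` (loss trace) and `simulate`
(synthesis) methods.

* **Generator**: per-timestep i.i.d. standard-normal noise (dimension 50 by
  default) concatenated with a per-timestep one-hot label, through two
  stacked LSTM layers (width 128 by default) and a per-timestep sigmoid
  head emitting the six channels — so any output lies in [0, 1]^(60×6) by
  construction, trained or not.
* **Discriminator**: window plus broadcast one-hot label through two
  stacked LSTM layers (128/64), last hidden state to a sigmoid real/fake
  score.
* **Losses**: non-saturating adversarial loss, plus a diversity-sensitive
  penalty on paired draws within each batch,
  `−min(τ, ‖w₁−w₂‖/‖z₁−z₂‖)` with cap τ = 1, weighted by λ = 8. The penalty
  rewards output spread per unit of latent spread and discourages mode
  collapse; pairs whose ratio exceeds the cap contribute a constant (no
  gradient).
* **Defaults**: Adam at 2×10⁻⁴, batch 64, 1600 epochs.

`synthesize_subjects()` draws subject-sized cohorts: 36 one-minute windows
per synthetic subject with exactly `round(0.30 × 36) = 11` stress windows
(30.6%), labels shuffled, windows generated conditioned on them.

All training runs on a small reverse-mode autodiff engine written for this
package (no deep-learning framework is required at runtime); LSTM layers
are fused tape nodes with hand-derived backpropagation-through-time, and
every operator's gradient is validated against central finite differences
in the test suite.

## Differential privacy

The DP-CGAN privatizes **only the discriminator** — the generator never
touches real data directly, so its ordinary Adam updates are post-processing
of the discriminator's privatized signal. The discriminator's updates use
DP-SGD mechanics: per-example gradients (batch size = microbatch count = 8,
so clipping is exactly per-example), global-L2 clipping at C = 1.0, and
Gaussian noise with multiplier σ, under Poisson subsampling (the data loader
samples each window independently with probability q = batch/n when DP is
on, matching the accountant's model).

Accounting uses a Rényi-DP accountant for the subsampled Gaussian mechanism
over an integer order grid (2…128 densely, then every 8 up to 1024),
converted to (ε, δ) with the tight conversion; the q = 1, single-step limit
is cross-checked against the closed-form analytic Gaussian mechanism in the
tests. `calibrate_noise()` binary-searches the smallest σ in [0.3, 100]
whose accounted spend stays at or below the target ε ∈ {10, 1, 0.1}.

Two accounting conventions matter:

* **Unique-window accounting.** Overlapping 30-s sliding windows duplicate
  the underlying seconds rather than adding unique ones, so the accountant
  uses the unique (stride-60) window count n ≈ 496 while doubling the
  accounted epochs (actual training still runs its configured 420 epochs
  over the sliding set). `sliding_window_accounting()` encodes this rule.
* **δ from n**: the largest power of ten strictly below 1/n — 10⁻³ at
  n = 496 (`select_delta()`).

## Quality evaluation

* `correlation_with_p()`: Pearson r (exact closed form) with two-sided
  t-transform p-values over the 6 channels + window label, computed on
  per-second values with the window label repeated per second (per-window
  means available via a flag). Zero-variance columns are recorded as r = 0,
  p = 1 with a flag.
* `c2st()`: classifier two-sample test with a Gaussian Naive-Bayes model on
  flattened 360-value windows, equal pools (downsampling the larger side),
  50/50 train/test split, accuracy reported overall and per label stratum.
  Held-out accuracy near 0.5 means the sets are indistinguishable.
* `embed_2d()`: PCA fitted on the real windows only (both sets projected;
  per-channel loadings summed over the 60 seconds), or exact t-SNE
  (perplexity 30, fixed seed) as a visualization contract.
* `density_compare()`: per-stratum histogram densities over [0, 1].
* `avg_pct_change()`: `100·|a−b| / ((a+b)/2)`, the symmetric percentage
  change used for per-channel spectral-power contrasts.

**On the C2ST null.** The 0.5 calibration holds when the two pools are
exchangeable — e.g. two disjoint window samples from one cohort, which is
how the package's null checks construct them. Two *independently generated*
small cohorts are not identically distributed at the window level: with a
handful of subjects per side, subject-specific baselines differ between
cohorts, and a classifier detects that difference (we measure ≈ 0.77
accuracy for 7-subject cohorts). The same effect appears with real data:
held-out real subjects score well above 0.5 against other real subjects.
A C2ST between small disjoint cohorts is a subject-level two-sample test,
not a calibration of the statistic.

## Spectral features and classifiers

`featurize_window()` converts each 60-s window to a 6×210 spectrum matrix:
per channel, subwindows of a channel-specific length slide across the
window, each subwindow's one-sided magnitude spectrum is zero-padded to 210
points, and all subwindow spectra are averaged. The channel configuration
ties the upper frequency bound to the subwindow length so that their product
is always 210 (ACC: 0–30 Hz / 7 s; BVP and EDA: 0–7 Hz / 30 s; TEMP:
0–6 Hz / 35 s); bins beyond the data's Nyquist are exact zeros and the DC
bin is retained. The configured 0.25-s subwindow stride is finer than 1 Hz
data permit, so the effective stride is one sample at the data rate (the
recorded resolution of that ambiguity); no windowing taper is applied.
"Spectrum" means magnitude; the baseline's "spectral power" uses squared
magnitudes (`power = TRUE`).

Three classifiers consume the spectra (`stress_classifier()`):

* **CNN**: three 1-D convolution blocks over the 210-point axis (widths
  32/64/128, kernel 5, max-pool 2), dense 128, sigmoid; 10 epochs.
* **CNN-LSTM**: the same convolutional stack with LSTM layers of widths 128
  and 64 inserted between the convolutional part and the dense layers;
  20 epochs.
* **TSCT**: a small transformer treating the 6×210 input as a 6-token
  sequence (model width 64, 4 heads, 2 encoder blocks); 110 epochs.

All train with inverse-class-frequency weights (normalized to mean 1),
Adam at 10⁻³, batch 50, and a fixed 0.5 decision threshold; degenerate
precision/recall (zero denominators) are reported as 0 with a flag. Exact
CNN/TSCT layer stacks are stated assumptions (the originating architectures
are described elsewhere at coarser granularity); every dimension is
configurable.

## LOSO evaluation harness

`run_experiment()` runs leave-one-subject-out cross-validation: one model
per subject, trained on the remaining subjects, tested on the held-out one;
per-fold metrics are averaged (unweighted — subjects have near-equal
durations), and whole LOSO runs are repeated (default 10) with derived
seeds. Strategies: **ORIG** (real fold data), **TSTR** (synthetic only),
**AUGM** (real + synthetic). Generators are trained per fold, excluding the
test subject (a `shared_gan` shortcut exists for cheap runs and is flagged
as not LOSO-conform in the report); synthetic cohorts are regenerated per
repeat. Classifiers train on stride-60 windows of real data; generators may
train on stride-30 windows.

`baseline_signal_sweep()` provides the non-deep baseline: logistic
regression on per-window mean spectral power for each of the 63 non-empty
channel subsets under the same LOSO protocol, plus the all-channel model's
coefficients and each channel's average percentage change between stress
and non-stress.

## Numerical choices and limitations

* Test-time problem sizes: the suite trains the GAN for 50 epochs on an
  8-subject cohort at reduced widths (32/(32, 16), latent 16), and the
  classifiers on small synthetic spectra; these sizes are the package's
  chosen test scale, and scientific defaults (widths 128/(128, 64), 1600
  epochs, λ = 8) remain the paper-scale configuration.
* σ calibration: bisection, 60 iterations over [0.3, 100]; unreachable
  budgets raise an error rather than silently clamping.
* The RDP→(ε, δ) conversion is an upper bound ~8–10% above the analytic
  Gaussian mechanism in the single-step limit; privacy claims are therefore
  conservative.
* Determinism: every stochastic routine takes or derives a seed; training
  is bit-reproducible given the seed.
* The exact t-SNE is O(n²) and intended for the few hundred windows of the
  quality reports.
* The per-fold GAN training of a full 15-fold × 10-repeat experiment at
  paper-scale settings is computationally heavy by design; the harness is
  structured for it, but the package's own checks run reduced
  configurations.
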
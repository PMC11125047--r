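Package: wearsynth
Title: Privacy-Preserving Synthesis of Wearable Stress-Detection Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating, evaluating and using synthetic multimodal
    smartwatch sensor data for stress detection. Provides an Empatica-E4-like
    synthetic cohort generator, a preparation pipeline (Fourier-method
    resampling to 1 Hz, label merging, min-max normalization, sliding 60-s
    windows), a conditional GAN over labeled signal windows with an LSTM
    discriminator and a diversity-sensitive regularizer, differentially
    private training via per-example gradient clipping and Gaussian noising
    with a Renyi-DP accountant, a synthetic-data quality suite (classifier
    two-sample test, Pearson correlation with p-values, PCA/t-SNE embeddings,
    density comparisons), FFT spectral featurization, CNN / CNN-LSTM /
    transformer stress classifiers, and a leave-one-subject-out evaluation
    harness supporting train-synthetic-test-real and augmentation strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
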
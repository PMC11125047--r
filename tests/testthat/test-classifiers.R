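test_that("confusion-derived metrics follow the printed formulas", {
  m <- confusion_metrics(tp = 30, fp = 10, fn = 20, tn = 40)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-4)
  perfect <- confusion_metrics(10, 0, 0, 10)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  # all-negative predictions on mixed truth: flagged zeros, F1 = 0
  degen <- confusion_metrics(0, 0, 5, 5)
  expect_equal(degen$precision, 0)
  expect_equal(degen$f1, 0)
  expect_true("precision_undefined" %in% degen$flags)
  # identities on randomized tables
  set.seed(3)
  for (i in 1:20) {
    k <- sample(0:30, 4, replace = TRUE)
    mm <- confusion_metrics(k[1], k[2], k[3], k[4])
    P <- if (k[1] + k[2] == 0) 0 else k[1] / (k[1] + k[2])
    R <- if (k[1] + k[3] == 0) 0 else k[1] / (k[1] + k[3])
    expect_equal(mm$f1, if (P + R == 0) 0 else 2 * P * R / (P + R))
    expect_true(mm$f1 >= min(P, R) - 1e-12 && mm$f1 <= max(P, R) + 1e-12)
  }
})

test_that("the CNN learns linearly separable toy spectra", {
  tr <- toy_spectra(60)
  cfg <- classifier_config("cnn", epochs = 6L, conv_widths = c(8L, 16L),
                           dense_width = 16L, batch_size = 20L, seed = 1L)
  m <- stress_classifier(tr, cfg)
  expect_gt(evaluate_classifier(m, tr)$accuracy, 0.95)
  expect_gt(evaluate_classifier(m, toy_spectra(40, seed = 9))$accuracy, 0.95)
})

test_that("training is deterministic and rejects single-class input", {
  tr <- toy_spectra(40)
  cfg <- classifier_config("cnn", epochs = 2L, conv_widths = c(4L, 8L),
                           dense_width = 8L, batch_size = 20L, seed = 6L)
  m1 <- stress_classifier(tr, cfg)
  m2 <- stress_classifier(tr, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(evaluate_classifier(m1, tr), evaluate_classifier(m2, tr))
  ones <- tr; ones$labels <- rep(1L, length(tr$labels))
  expect_error(stress_classifier(ones, cfg), "both classes")
})

test_that("the hybrid model places 128/64-wide recurrent layers after the convolutions", {
  cfg <- classifier_config("cnn_lstm")
  expect_equal(cfg$lstm_widths, c(128L, 64L))
  # architecture introspection on a tiny trained instance
  tr <- toy_spectra(30)
  tiny <- classifier_config("cnn_lstm", epochs = 1L, conv_widths = c(4L, 8L),
                            dense_width = 8L, lstm_widths = c(12L, 6L),
                            batch_size = 15L, seed = 2L)
  m <- stress_classifier(tr, tiny)
  expect_equal(m$architecture$kind, "cnn_lstm")
  expect_equal(m$architecture$lstm_widths, c(12L, 6L))
  # the recurrent weights sit between conv and dense parameters
  expect_equal(dim(m$params[["lstm1.W"]]), c(8L + 12L, 4L * 12L))
  expect_equal(dim(m$params[["lstm2.W"]]), c(12L + 6L, 4L * 6L))
  nms <- names(m$params)
  expect_lt(max(grep("^conv", nms)), min(grep("^lstm", nms)))
  expect_gt(min(grep("^dense", nms)), max(grep("^lstm", nms)))
})

test_that("the transformer and hybrid classifiers also fit the toy task", {
  tr <- toy_spectra(60)
  tcfg <- classifier_config("tsct", epochs = 15L, d_model = 16L, n_heads = 2L,
                            n_blocks = 1L, ffn_width = 16L, batch_size = 20L,
                            seed = 1L)
  expect_gt(evaluate_classifier(stress_classifier(tr, tcfg), tr)$accuracy,
            0.95)
  hcfg <- classifier_config("cnn_lstm", epochs = 25L, conv_widths = c(8L, 16L),
                            dense_width = 16L, lstm_widths = c(16L, 8L),
                            batch_size = 20L, learning_rate = 3e-3, seed = 1L)
  expect_gt(evaluate_classifier(stress_classifier(tr, hcfg), tr)$accuracy,
            0.95)
})

test_that("private training clips per example and stays inside its budget", {
  tr <- toy_spectra(40)
  spec <- privacy_spec(epsilon = 5, unique_n = 40L, effective_epochs = 2L,
                       delta = 1e-2, batch_size = 10L, epochs = 2L)
  # round-trip: the accounted spend of the configured run is within budget
  spent <- epsilon_spent(spec$sigma, 10 / 40, ceiling(2 * 40 / 10), 1e-2)
  expect_lte(spent, 5)
  cfg <- classifier_config("cnn", epochs = 2L, conv_widths = c(4L, 8L),
                           dense_width = 8L, batch_size = 10L, privacy = spec,
                           seed = 4L)
  m <- stress_classifier(tr, cfg)
  expect_true(m$private)
  expect_true(all(is.finite(m$loss_trace)))
  # epsilon = Inf degrades to non-private training with a notice
  inf_cfg <- classifier_config("cnn", epochs = 1L, conv_widths = c(4L, 8L),
                               dense_width = 8L, batch_size = 20L,
                               privacy = privacy_spec(epsilon = Inf),
                               seed = 4L)
  expect_message(m2 <- stress_classifier(tr, inf_cfg), "non-privately")
  expect_false(m2$private)
})
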
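test_that("Fourier resampling preserves DC and in-band sinusoids", {
  # constant signal: every resampled value equals the constant
  ses <- list(subject_id = "A",
              signals = stats::setNames(lapply(e4_signals, function(s)
                list(rate = 4, values = rep(2.5, 40))), e4_signals),
              labels = rep(0L, 10))
  class(ses) <- "raw_session"
  a <- resample_to_1hz(ses)
  expect_equal(nrow(a$signals), 10L)
  expect_equal(unname(a$signals[, "EDA"]), rep(2.5, 10), tolerance = 1e-10)

  # 0.2 Hz unit sinusoid sampled at 32 Hz survives downsampling to 1 Hz
  x32 <- sin(2 * pi * 0.2 * seq(0, 60 - 1 / 32, by = 1 / 32))
  y <- wearsynth:::fourier_resample(x32, 60)
  ref <- sin(2 * pi * 0.2 * (0:59))
  expect_lt(max(abs(y - ref)), 0.05)
  sp <- Mod(stats::fft(y))
  expect_equal(which.max(sp[2:30]), 12L)  # 0.2 Hz = bin 12 over 60 s

  # 36-min session: 2160 aligned samples per channel
  a2 <- resample_to_1hz(generate_session(fixture_spec(seed = 3), "S"))
  expect_equal(dim(a2$signals), c(2160L, 6L))
})

test_that("resampling rejects empty or truncated signals", {
  ses <- generate_session(fixture_spec(seed = 3, duration_s = 150), "S")
  bad <- ses; bad$signals$BVP$values <- numeric(0)
  expect_error(resample_to_1hz(bad), "BVP")
  short <- ses; short$signals$EDA$values <- short$signals$EDA$values[1:10]
  expect_error(resample_to_1hz(short), "shorter")
})

test_that("label merging maps 3 states onto binary stress and is idempotent", {
  expect_equal(merge_labels(c(0L, 2L, 1L, 1L, 0L)), c(0L, 0L, 1L, 1L, 0L))
  expect_equal(merge_labels(rep(1L, 5)), rep(1L, 5))
  expect_setequal(unique(merge_labels(c(0L, 1L, 2L))), c(0L, 1L))
  b <- merge_labels(c(0L, 2L, 1L))
  expect_identical(merge_labels(b), b)
  expect_error(merge_labels(c(0L, 3L, 1L)), "position.*2")
})

test_that("min-max normalization scales to [0,1] with reusable statistics", {
  mk <- function(vals) {
    m <- matrix(rep(vals, 6), ncol = 6)
    colnames(m) <- e4_signals
    structure(list(subject_id = "A", signals = m,
                   labels = rep(0L, length(vals))),
              class = "aligned_session")
  }
  out <- minmax_normalize(list(mk(c(0, 5, 10))))
  expect_equal(unname(out$sessions[[1]]$signals[, 1]), c(0, 0.5, 1))
  # constant channel maps to zeros
  outc <- minmax_normalize(list(mk(rep(4, 3))))
  expect_equal(unname(outc$sessions[[1]]$signals[, 1]), c(0, 0, 0))
  # re-running on the original sessions with the stored stats reproduces
  # the first result exactly
  again <- minmax_normalize(list(mk(c(0, 5, 10))), out$stats)
  expect_equal(again$sessions[[1]]$signals, out$sessions[[1]]$signals)
  expect_identical(again$stats, out$stats)
  # foreign values are clipped into [0,1] under given stats
  clip <- minmax_normalize(list(mk(c(-5, 20, 5))), out$stats)
  expect_true(all(clip$sessions[[1]]$signals >= 0 &
                    clip$sessions[[1]]$signals <= 1))
})

test_that("window counts follow floor((T-60)/stride)+1 across a sweep", {
  mk_aligned <- function(T, labels = rep(0L, T)) {
    m <- matrix(runif(T * 6), T, 6); colnames(m) <- e4_signals
    structure(list(subject_id = "A", signals = m, labels = labels),
              class = "aligned_session")
  }
  for (T in c(60L, 61L, 89L, 90L, 119L, 120L, 600L, 2160L)) {
    for (stride in c(30L, 60L)) {
      ws <- slice_windows(mk_aligned(T), stride_s = stride)
      expect_equal(length(ws$labels), (T - 60L) %/% stride + 1L,
                   info = sprintf("T=%d stride=%d", T, stride))
    }
  }
  expect_equal(length(slice_windows(mk_aligned(2160L), stride_s = 60L)$labels),
               36L)
  expect_equal(length(slice_windows(mk_aligned(2160L), stride_s = 30L)$labels),
               71L)
  expect_error(slice_windows(mk_aligned(59L)), "too short")
})

test_that("window labels follow the majority vote with the stress tie rule", {
  mk_aligned <- function(labels) {
    T <- length(labels)
    m <- matrix(0.5, T, 6); colnames(m) <- e4_signals
    structure(list(subject_id = "A", signals = m, labels = labels),
              class = "aligned_session")
  }
  expect_equal(slice_windows(mk_aligned(c(rep(1L, 40), rep(0L, 20))))$labels,
               1L)
  expect_equal(slice_windows(mk_aligned(c(rep(1L, 20), rep(0L, 40))))$labels,
               0L)
  tie <- c(rep(1L, 30), rep(0L, 30))
  expect_equal(slice_windows(mk_aligned(tie))$labels, 1L)
  expect_equal(slice_windows(mk_aligned(tie), tie = 0L)$labels, 0L)
})

test_that("window sets round-trip through the container plus CSV index", {
  ws <- toy_window_set(6)
  path <- file.path(withr::local_tempdir(), "ws")
  write_windowset(ws, path)
  back <- read_windowset(path)
  expect_equal(back, ws)
  idx <- utils::read.csv(paste0(path, ".index.csv"))
  expect_equal(nrow(idx), 6L)
  expect_equal(idx$label, ws$labels)
  expect_equal(idx$subject, ws$subject)
})

test_that("the pipeline emits [0,1] windows with per-window provenance", {
  ws <- small_windows(4)
  expect_s3_class(ws, "window_set")
  expect_true(all(ws$windows >= 0 & ws$windows <= 1))
  expect_length(unique(ws$subject), 4L)
  expect_true(all(ws$labels %in% 0:1))
  # majority labels agree with recomputing from the aligned sessions
  expect_equal(dim(ws$windows)[2:3], c(60L, 6L))
})
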
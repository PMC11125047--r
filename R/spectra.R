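# FFT spectral featurization: per-channel subwindows slide across a 60-s
# window, each subwindow's one-sided magnitude spectrum is zero-padded to 210
# frequency points, and all subwindow spectra are averaged into a single
# 6 x 210 feature matrix per window.

#' Spectral featurization configuration
#'
#' Per channel: the upper frequency bound (Hz) and subwindow length (s),
#' chosen so that their product is always the 210 spectrum points the
#' classifiers consume; plus the subwindow stride.
#'
#' @param stride_s Subwindow stride in seconds (effective stride is at least
#'   one sample at the data rate).
#' @param n_points Points per spectrum.
#' @return Object of class `spectra_config` with a per-channel table.
#' @export
spectra_config <- function(stride_s = 0.25, n_points = 210L) {
  tab <- data.frame(
    signal = e4_signals,
    upper_hz = c(30, 30, 30, 7, 7, 6),
    subwindow_s = c(7, 7, 7, 30, 30, 35))
  stopifnot(all(tab$upper_hz * tab$subwindow_s == n_points))
  structure(list(table = tab, stride_s = stride_s,
                 n_points = as.integer(n_points)),
            class = "spectra_config")
}

#' One-sided magnitude spectrum of a subwindow, padded to 210 points
#'
#' Bins are indexed 0..209 at spacing `upper_hz / 210` Hz (which equals the
#' subwindow's own DFT resolution `1 / subwindow_s`); bins beyond the data's
#' Nyquist frequency are exact zeros, the DC bin is retained.
#'
#' @param samples Subwindow samples at rate `fs`.
#' @param fs Sampling rate in Hz.
#' @param upper_hz Upper frequency bound of the channel.
#' @param n_points Spectrum length (210).
#' @return Numeric vector of `n_points` non-negative magnitudes.
#' @export
fft_subwindow_spectrum <- function(samples, fs, upper_hz, n_points = 210L) {
  n <- length(samples)
  if (n == 0) stop("empty subwindow", call. = FALSE)
  X <- Mod(stats::fft(samples))
  n_onesided <- n %/% 2L + 1L           # DC .. Nyquist
  out <- numeric(n_points)
  keep <- min(n_onesided, n_points)
  out[seq_len(keep)] <- X[seq_len(keep)]
  out
}

#' Featurize one 60-s window into a 6 x 210 spectrum matrix
#'
#' Per channel, slides subwindows of the configured length across the window
#' (stride rounded up to at least one sample), computes each subwindow's
#' padded magnitude spectrum, and averages them.
#'
#' @param window 60 x 6 matrix at 1 Hz (channel order [e4_signals]).
#' @param cfg A [spectra_config()].
#' @param fs Sampling rate of the window rows (1 Hz in this pipeline).
#' @param power Return squared magnitudes (spectral power) instead of
#'   magnitudes.
#' @return 6 x 210 non-negative feature matrix (rows named by channel).
#' @export
featurize_window <- function(window, cfg = spectra_config(), fs = 1,
                             power = FALSE) {
  stopifnot(nrow(window) == 60L, ncol(window) == 6L)
  stride <- max(1L, round(cfg$stride_s * fs))
  out <- matrix(0, 6L, cfg$n_points, dimnames = list(e4_signals, NULL))
  for (c in seq_len(6L)) {
    len <- as.integer(cfg$table$subwindow_s[c] * fs)
    if (len > nrow(window))
      stop(sprintf("subwindow (%d samples) longer than window", len),
           call. = FALSE)
    starts <- seq(0L, nrow(window) - len, by = stride)
    acc <- numeric(cfg$n_points)
    for (s in starts) {
      sp <- fft_subwindow_spectrum(window[s + seq_len(len), c], fs,
                                   cfg$table$upper_hz[c], cfg$n_points)
      acc <- acc + if (power) sp^2 else sp
    }
    out[c, ] <- acc / length(starts)
  }
  out
}

#' Featurize every window of a window set
#'
#' @param ws A [window_set()].
#' @param cfg A [spectra_config()].
#' @param power Use squared magnitudes.
#' @return Object of class `spectrum_set`: `features` array `N x 6 x 210`,
#'   `labels`, `subject`.
#' @export
featurize_windows <- function(ws, cfg = spectra_config(), power = FALSE) {
  n <- length(ws$labels)
  feats <- array(NA_real_, c(n, 6L, cfg$n_points))
  for (i in seq_len(n))
    feats[i, , ] <- featurize_window(ws$windows[i, , ], cfg, power = power)
  structure(list(features = feats, labels = ws$labels, subject = ws$subject),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d windows x 6 channels x %d frequency points\n",
              length(x$labels), dim(x$features)[3]))
  invisible(x)
}

# Per-window, per-channel mean spectral power (baseline features).
mean_spectral_power <- function(ws, cfg = spectra_config()) {
  n <- length(ws$labels)
  out <- matrix(NA_real_, n, 6L, dimnames = list(NULL, e4_signals))
  for (i in seq_len(n))
    out[i, ] <- rowMeans(featurize_window(ws$windows[i, , ], cfg,
                                          power = TRUE))
  out
}
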
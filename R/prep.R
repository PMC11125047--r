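# Preparation pipeline: multi-rate raw sessions -> aligned, binary-labeled,
# min-max-normalized 60-s windows. Four steps: Fourier-method resampling to
# 1 Hz, merging neutral+amusement into non-stress, [0,1] min-max
# normalization, and 60-s windowing with an optional 30-s slide.

# Fourier-method resampling (spectrum truncation/zero-padding), equivalent to
# the classic FFT resampler: keep the lowest `m` frequencies of the length-n
# DFT, inverse-transform, rescale by m/n.
fourier_resample <- function(x, m) {
  n <- length(x)
  if (n == 0L) stop("cannot resample an empty signal", call. = FALSE)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  nyq <- min(m, n) %/% 2L
  Y[seq_len(nyq + 1L)] <- X[seq_len(nyq + 1L)]
  if (nyq > 1L)
    Y[m - seq_len(nyq - 1L) + 1L] <- X[n - seq_len(nyq - 1L) + 1L]
  if (min(m, n) %% 2L == 0L && m < n) {
    # split the Nyquist bin symmetrically when downsampling to an even length
    Y[nyq + 1L] <- X[nyq + 1L] / 2
    Y[m - nyq + 1L] <- Y[m - nyq + 1L] + Conj(X[nyq + 1L]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a raw session to an aligned 1 Hz time base
#'
#' Downsamples every channel to exactly one sample per second using the
#' Fourier method (truncate the spectrum to the new bandwidth and
#' inverse-transform), aligning all six channels on the same per-second grid
#' as the label track.
#'
#' @param session A `raw_session` (see [generate_session()]).
#' @return An `aligned_session`: list with `subject_id`, a `T x 6` signal
#'   matrix (columns in [e4_signals] order), and the per-second `labels`.
#' @export
resample_to_1hz <- function(session) {
  T <- length(session$labels)
  if (T == 0L) stop("session has an empty label track", call. = FALSE)
  cols <- lapply(e4_signals, function(s) {
    v <- session$signals[[s]]
    if (is.null(v) || length(v$values) == 0L)
      stop(sprintf("signal %s is empty", s), call. = FALSE)
    n_whole <- as.integer(v$rate * T)
    x <- v$values
    if (length(x) < n_whole)
      stop(sprintf("signal %s shorter than the label track (%d < %d samples)",
                   s, length(x), n_whole), call. = FALSE)
    fourier_resample(x[seq_len(n_whole)], T)
  })
  sigmat <- do.call(cbind, cols)
  colnames(sigmat) <- e4_signals
  structure(list(subject_id = session$subject_id, signals = sigmat,
                 labels = as.integer(session$labels)),
            class = "aligned_session")
}

#' Merge the 3-state affect labels into binary stress labels
#'
#' Stress (code 1) stays 1; neutral (0) and amusement (2) become the common
#' non-stress label 0.
#'
#' @param labels3 Integer vector of codes in \{0, 1, 2\}.
#' @return Integer vector of the same length with values in \{0, 1\}.
#' @export
merge_labels <- function(labels3) {
  bad <- which(!(labels3 %in% c(0L, 1L, 2L)))
  if (length(bad))
    stop(sprintf("unknown label code at position(s) %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  as.integer(labels3 == 1L)
}

#' Min-max normalize aligned sessions to [0,1]
#'
#' Computes per-channel global minima and maxima over all provided sessions
#' (or applies supplied statistics, clipping to [0,1]) and rescales each
#' channel. A constant channel (max equal to min) maps to all zeros.
#'
#' @param sessions List of `aligned_session` objects.
#' @param stats Optional normalization statistics from a previous call
#'   (a list with `min` and `max`, each a named 6-vector).
#' @return List with `sessions` (rescaled) and `stats` (the statistics used).
#' @export
minmax_normalize <- function(sessions, stats = NULL) {
  if (length(sessions) == 0L) stop("no sessions supplied", call. = FALSE)
  if (is.null(stats)) {
    allmat <- do.call(rbind, lapply(sessions, `[[`, "signals"))
    stats <- list(min = apply(allmat, 2, min), max = apply(allmat, 2, max))
  }
  rng <- stats$max - stats$min
  out <- lapply(sessions, function(ses) {
    m <- ses$signals
    for (j in seq_along(e4_signals)) {
      if (rng[j] == 0) m[, j] <- 0
      else m[, j] <- pmin(1, pmax(0, (m[, j] - stats$min[j]) / rng[j]))
    }
    ses$signals <- m
    ses
  })
  list(sessions = out, stats = stats)
}

#' Construct a window set
#'
#' The common currency of the package: `N` labeled 60-second, six-channel
#' windows.
#'
#' @param windows Numeric array `N x 60 x 6`.
#' @param labels Integer vector of `N` binary window labels.
#' @param subject Character vector of `N` subject ids.
#' @param stride_s Stride in seconds the windows were cut with.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, subject, stride_s = 60L) {
  stopifnot(length(dim(windows)) == 3L, dim(windows)[2] == 60L,
            dim(windows)[3] == 6L, dim(windows)[1] == length(labels),
            length(subject) == length(labels))
  structure(list(windows = windows, labels = as.integer(labels),
                 subject = as.character(subject),
                 stride_s = as.integer(stride_s)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows (60 s x 6 channels), stride %d s\n",
              length(x$labels), x$stride_s))
  cat(sprintf("  subjects: %d | stress share: %.1f%%\n",
              length(unique(x$subject)), 100 * mean(x$labels)))
  invisible(x)
}

# Concatenate window sets.
#' @export
c.window_set <- function(...) {
  parts <- list(...)
  arr <- do.call(abind3, lapply(parts, `[[`, "windows"))
  window_set(arr, unlist(lapply(parts, `[[`, "labels")),
             unlist(lapply(parts, `[[`, "subject")),
             parts[[1]]$stride_s)
}

# rbind for N x 60 x 6 arrays along the first axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[2:3]
  n <- sum(vapply(parts, function(a) dim(a)[1], 0L))
  out <- array(NA_real_, c(n, d))
  at <- 0L
  for (a in parts) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

# subset a window_set by index
ws_subset <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
             ws$subject[idx], ws$stride_s)
}

#' Cut an aligned session into labeled 60-s windows
#'
#' Windows are 0-based half-open intervals `[k*stride, k*stride + 60)`; the
#' trailing partial window is dropped, giving `floor((T-60)/stride) + 1`
#' windows. Each window's label is the majority vote of its 60 per-second
#' binary labels; a 30/30 tie is assigned to stress by default (favoring
#' detector sensitivity).
#'
#' @param session An `aligned_session` with binary labels.
#' @param window_s Window length in seconds (60).
#' @param stride_s Stride in seconds, 30 or 60.
#' @param tie Label assigned on a 30/30 tie (default 1).
#' @return A [window_set()].
#' @export
slice_windows <- function(session, window_s = 60L, stride_s = 30L, tie = 1L) {
  T <- nrow(session$signals)
  if (T < window_s)
    stop(sprintf("session too short for a %d-s window (T=%d)", window_s, T),
         call. = FALSE)
  starts <- seq(0L, T - window_s, by = stride_s)
  n <- length(starts)
  arr <- array(NA_real_, c(n, window_s, 6L))
  labs <- integer(n)
  for (i in seq_len(n)) {
    idx <- starts[i] + seq_len(window_s)
    arr[i, , ] <- session$signals[idx, ]
    s <- sum(session$labels[idx])
    labs[i] <- if (s * 2L == window_s) as.integer(tie) else
      as.integer(s * 2L > window_s)
  }
  window_set(arr, labs, rep(session$subject_id, n), stride_s)
}

#' Write or read a window set
#'
#' Stores the window array in R's portable serialized container next to a
#' plain-text CSV index (`subject,window_start_s,label`) for inspection by
#' other tools.
#'
#' @param ws A [window_set()].
#' @param path Basename path; writes `<path>.rds` and `<path>.index.csv`.
#' @return `path` (write) or the restored `window_set` (read), invisibly.
#' @export
write_windowset <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  saveRDS(unclass(ws), paste0(path, ".rds"))
  starts <- stats::ave(seq_along(ws$labels), ws$subject,
                       FUN = function(i) (seq_along(i) - 1L) * ws$stride_s)
  utils::write.csv(data.frame(subject = ws$subject, window_start_s = starts,
                              label = ws$labels),
                   paste0(path, ".index.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_windowset
#' @export
read_windowset <- function(path) {
  x <- readRDS(paste0(path, ".rds"))
  window_set(x$windows, x$labels, x$subject, x$stride_s)
}

#' Run the full preparation pipeline over a cohort
#'
#' Resamples each raw session to 1 Hz, merges labels to binary, normalizes
#' channels to [0,1] with cohort-level statistics (or supplied ones), and
#' cuts sliding windows.
#'
#' @param cohort List of `raw_session` objects.
#' @param stride_s Window stride in seconds (30 or 60).
#' @param stats Optional normalization statistics (e.g. from the training
#'   fold, to scale a held-out subject without leakage).
#' @return List with `windows` (a [window_set()] pooled over subjects) and
#'   `stats` (normalization statistics used).
#' @export
prepare_cohort <- function(cohort, stride_s = 30L, stats = NULL) {
  aligned <- lapply(cohort, function(ses) {
    a <- resample_to_1hz(ses)
    a$labels <- merge_labels(a$labels)
    a
  })
  norm <- minmax_normalize(aligned, stats)
  sets <- lapply(norm$sessions, slice_windows, stride_s = stride_s)
  list(windows = do.call(c, sets), stats = norm$stats)
}
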
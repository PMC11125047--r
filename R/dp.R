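# Differential-privacy machinery: per-example gradient clipping, Gaussian
# noising, a Renyi-DP accountant for the Poisson-subsampled Gaussian
# mechanism, noise calibration, and the unique-window accounting rule for
# overlapping sliding windows.

rdp_orders <- c(2:128, seq(136L, 1024L, by = 8L))

# Per-step Renyi divergence bound of the Poisson-subsampled Gaussian
# mechanism at integer order alpha (log-space binomial expansion).
rdp_subsampled_gaussian <- function(alpha, q, sigma) {
  if (q >= 1) return(alpha / (2 * sigma^2))
  k <- 0:alpha
  terms <- lchoose(alpha, k) + (alpha - k) * log1p(-q) + k * log(q) +
    k * (k - 1) / (2 * sigma^2)
  m <- max(terms)
  (m + log(sum(exp(terms - m)))) / (alpha - 1)
}

# Convert accumulated RDP to (epsilon, delta) with the tight conversion of
# Balle et al. (2020); minimized over the order grid.
rdp_to_epsilon <- function(rdp, orders, delta) {
  eps <- rdp + log((orders - 1) / orders) - (log(delta) + log(orders)) /
    (orders - 1)
  max(0, min(eps))
}

#' Privacy loss of repeated subsampled Gaussian updates
#'
#' Renyi-DP (moments-accountant style) bound on the privacy budget epsilon
#' spent by `steps` applications of the Poisson-subsampled Gaussian mechanism
#' with sampling rate `q` and noise multiplier `sigma`, converted to
#' `(epsilon, delta)`.
#'
#' @param sigma Noise multiplier (noise sd is `sigma * clip_norm`).
#' @param q Sampling rate in (0, 1] (batch size over unique examples).
#' @param steps Number of noisy updates.
#' @param delta Target delta.
#' @return The spent epsilon (``Inf`` when `sigma` is 0).
#' @export
epsilon_spent <- function(sigma, q, steps, delta) {
  if (sigma <= 0) return(Inf)
  stopifnot(q > 0, q <= 1, steps >= 1, delta > 0, delta < 1)
  rdp <- vapply(rdp_orders, rdp_subsampled_gaussian, 0, q = q, sigma = sigma)
  rdp_to_epsilon(steps * rdp, rdp_orders, delta)
}

#' Choose delta from the unique training-set size
#'
#' Returns the largest power of ten strictly below `1/unique_n`, encoding the
#' convention that delta should be well below the inverse dataset size.
#'
#' @param unique_n Number of unique training examples (>= 2).
#' @return A power of ten.
#' @export
select_delta <- function(unique_n) {
  stopifnot(unique_n >= 2)
  e <- floor(log10(1 / unique_n))
  if (10^e >= 1 / unique_n) e <- e - 1  # require strictly below
  10^e
}

#' Unique-window accounting for overlapping sliding windows
#'
#' Overlapping 30-s sliding windows duplicate the underlying seconds rather
#' than adding unique ones. Privacy accounting therefore uses the unique
#' (non-overlapping) window count, and doubles the accounted epochs to cover
#' the doubled sampling probability of each unique data point.
#'
#' @param n_windows_sliding Window count with the slide applied.
#' @param n_windows_unique Window count without the slide.
#' @return List with `unique_n` and `epoch_multiplier` (2 when sliding
#'   enlarged the set, 1 otherwise).
#' @export
sliding_window_accounting <- function(n_windows_sliding, n_windows_unique) {
  stopifnot(n_windows_sliding >= 1, n_windows_unique >= 1)
  if (n_windows_sliding < n_windows_unique)
    stop("sliding window count cannot be below the unique count", call. = FALSE)
  list(unique_n = n_windows_unique,
       epoch_multiplier = if (n_windows_sliding > n_windows_unique) 2L else 1L)
}

#' Calibrate the noise multiplier to a target privacy budget
#'
#' Binary search for the smallest noise multiplier sigma whose accounted
#' epsilon over the full training run is at or below the target.
#'
#' @param spec A [privacy_spec()] with finite `epsilon`.
#' @param lower,upper Search bracket for sigma.
#' @param iters Bisection iterations.
#' @return The calibrated sigma.
#' @export
calibrate_noise <- function(spec, lower = 0.3, upper = 100, iters = 60L) {
  if (!is.finite(spec$epsilon)) return(0)
  q <- spec$batch_size / spec$unique_n
  steps <- ceiling(spec$effective_epochs * spec$unique_n / spec$batch_size)
  eps_at <- function(s) epsilon_spent(s, q, steps, spec$delta)
  if (eps_at(upper) > spec$epsilon)
    stop(sprintf("target epsilon %.3g unreachable with sigma <= %g",
                 spec$epsilon, upper), call. = FALSE)
  if (eps_at(lower) <= spec$epsilon) return(lower)
  lo <- lower; hi <- upper
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (eps_at(mid) <= spec$epsilon) hi <- mid else lo <- mid
  }
  hi
}

#' Differential-privacy training specification
#'
#' Bundles the privacy budget and the mechanics of DP optimization:
#' per-example clip norm, batch/microbatch size, the unique-example count
#' used for accounting, accounted epochs, and the calibrated noise
#' multiplier.
#'
#' @param epsilon Target budget (`Inf` disables DP; typical finite choices
#'   10, 1, 0.1).
#' @param unique_n Unique training-example count used by the accountant.
#' @param effective_epochs Epochs used in accounting (actual epochs times the
#'   sliding-window multiplier of [sliding_window_accounting()]).
#' @param delta Privacy slack; defaults to [select_delta()] of `unique_n`.
#' @param clip_norm Per-example gradient clip bound C.
#' @param batch_size Batch size; microbatch count equals it, so clipping is
#'   exactly per-example.
#' @param learning_rate Learning rate used by DP training.
#' @param epochs Actual training epochs for the private run.
#' @return Object of class `privacy_spec` with the derived `sigma`.
#' @export
privacy_spec <- function(epsilon = 10, unique_n = 496L,
                         effective_epochs = 840L, delta = NULL,
                         clip_norm = 1.0, batch_size = 8L,
                         learning_rate = 1e-3, epochs = 420L) {
  if (!(is.infinite(epsilon) || epsilon > 0))
    stop_field("epsilon", "must be positive or Inf")
  if (clip_norm <= 0) stop_field("clip_norm", "must be positive")
  delta <- delta %||% select_delta(unique_n)
  if (delta <= 0 || delta >= 1) stop_field("delta", "must lie in (0,1)")
  if (delta >= 1 / unique_n)
    stop_field("delta", "must be below 1/unique_n")
  spec <- structure(
    list(epsilon = epsilon, delta = delta, clip_norm = clip_norm,
         batch_size = as.integer(batch_size), unique_n = as.integer(unique_n),
         effective_epochs = as.integer(effective_epochs),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         sigma = NA_real_),
    class = "privacy_spec")
  spec$sigma <- calibrate_noise(spec)
  spec
}

#' @export
print.privacy_spec <- function(x, ...) {
  cat(sprintf(
    "<privacy_spec> epsilon=%s delta=%.1e C=%.2f sigma=%.3f (n=%d, batch=%d, accounted epochs=%d)\n",
    format(x$epsilon), x$delta, x$clip_norm, x$sigma, x$unique_n,
    x$batch_size, x$effective_epochs))
  invisible(x)
}

# Global L2 norm of a named list of gradient matrices.
grad_global_norm <- function(g) {
  sqrt(sum(vapply(g, function(m) sum(m^2), 0)))
}

#' Clip per-example gradients to a global L2 norm bound
#'
#' @param grads List of per-example gradient sets; each element is a named
#'   list of matrices (one per parameter).
#' @param C Norm bound; gradients with global norm above C are rescaled to C,
#'   others pass unchanged.
#' @return The clipped list, same structure.
#' @export
clip_per_example <- function(grads, C) {
  stopifnot(C > 0)
  lapply(grads, function(g) {
    nrm <- grad_global_norm(g)
    if (nrm > C) lapply(g, function(m) m * (C / nrm)) else g
  })
}

# Sum clipped per-example gradients, add Gaussian noise sigma*C per
# coordinate, and average over the batch: the DP gradient estimate.
dp_aggregate <- function(clipped, sigma, C, batch) {
  nms <- names(clipped[[1]])
  out <- stats::setNames(vector("list", length(nms)), nms)
  for (nm in nms) {
    s <- Reduce(`+`, lapply(clipped, `[[`, nm))
    if (sigma > 0)
      s <- s + matrix(stats::rnorm(length(s), 0, sigma * C), nrow(s), ncol(s))
    out[[nm]] <- s / batch
  }
  out
}
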
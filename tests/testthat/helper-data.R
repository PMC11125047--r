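# Shared fixtures, built once per test run and memoized.

# internal tape primitives used by the gradient tests
tape_new <- wearsynth:::tape_new
tp_const <- wearsynth:::tp_const
tp_param <- wearsynth:::tp_param
tp_add <- wearsynth:::tp_add
tp_val <- wearsynth:::tp_val
tp_backward <- wearsynth:::tp_backward

.ws_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.ws_cache[[key]])) .ws_cache[[key]] <- force(expr)
  .ws_cache[[key]]
}

small_cohort <- function(n = 4L, seed = 21L) {
  cached(sprintf("cohort_%d_%d", n, seed),
         generate_cohort(fixture_spec(seed = seed), n))
}

small_windows <- function(n = 4L, seed = 21L, stride = 30L) {
  cached(sprintf("win_%d_%d_%d", n, seed, stride),
         prepare_cohort(small_cohort(n, seed), stride_s = stride)$windows)
}

# a tiny deterministic window_set built by hand (no pipeline)
toy_window_set <- function(n = 8L, seed = 1L) {
  set.seed(seed)
  arr <- array(runif(n * 60 * 6), c(n, 60, 6))
  window_set(arr, rep(0:1, length.out = n),
             rep(c("A", "B"), each = n / 2), 60L)
}

# linearly separable toy spectra: stress carries high bin-5 energy
toy_spectra <- function(n = 60L, seed = 4L, sep = 3) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  f <- array(abs(rnorm(n * 6 * 210, 0, 0.1)), c(n, 6, 210))
  f[y == 1, , 5] <- f[y == 1, , 5] + sep
  structure(list(features = f, labels = y,
                 subject = rep(c("A", "B"), length.out = n)),
            class = "spectrum_set")
}

tiny_gan_config <- function(epochs = 2L, seed = 3L, ...) {
  gan_config(epochs = epochs, g_width = 8L, d_widths = c(8L, 4L),
             noise_dim = 4L, batch_size = 16L, seed = seed, ...)
}

# finite-difference gradient checker over a tape-building closure
fd_max_rel_err <- function(build, params, n_coords = 5L, eps = 1e-5) {
  tp <- tape_new()
  ids <- lapply(params, function(p) tp_param(tp, p))
  loss <- build(tp, ids)
  g <- tp_backward(tp, loss)
  maxerr <- 0
  loss_at <- function(pp) {
    tp2 <- tape_new()
    ids2 <- lapply(pp, function(p) tp_param(tp2, p))
    as.numeric(tp_val(tp2, build(tp2, ids2)))
  }
  for (nm in names(params)) {
    gp <- g[[ids[[nm]]]]
    ks <- sample(length(params[[nm]]), min(n_coords, length(params[[nm]])))
    for (k in ks) {
      pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      maxerr <- max(maxerr, abs(num - gp[k]) / max(1e-4, abs(num), abs(gp[k])))
    }
  }
  maxerr
}
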
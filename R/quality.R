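# Synthetic-data quality suite: Pearson correlations with p-values, a
# Gaussian Naive-Bayes classifier two-sample test, 2-D embeddings (PCA fitted
# on real data; exact t-SNE), per-stratum density histograms, and the
# average-percentage-change statistic.

flatten_windows <- function(ws) {
  n <- dim(ws$windows)[1]
  matrix(ws$windows, n)  # N x 360, column blocks = channel-major seconds
}

#' Pearson correlations (with p-values) between channels and the label
#'
#' Pools per-second values over all windows of a window set and correlates
#' the six channels plus the window label (repeated per second). p-values use
#' the exact t-distribution transform of r. A zero-variance column is
#' recorded with r = 0, p = 1 and flagged.
#'
#' @param windows A [window_set()].
#' @param per_window Correlate per-window channel means instead of per-second
#'   values.
#' @return Object of class `correlation_report`: 7 x 7 matrices `r` and `p`,
#'   plus `flags` naming degenerate columns.
#' @export
correlation_with_p <- function(windows, per_window = FALSE) {
  stopifnot(inherits(windows, "window_set"))
  n_w <- length(windows$labels)
  if (n_w < 3) stop("need at least 3 windows", call. = FALSE)
  if (length(unique(windows$labels)) < 2)
    stop("both labels must be present", call. = FALSE)
  if (per_window) {
    mat <- cbind(apply(windows$windows, c(1, 3), mean), windows$labels)
  } else {
    # per-second rows: stack the 60 seconds of every window
    mat <- cbind(matrix(aperm(windows$windows, c(2, 1, 3)), n_w * 60L),
                 rep(windows$labels, each = 60L))
  }
  colnames(mat) <- c(e4_signals, "Label")
  k <- ncol(mat); n <- nrow(mat)
  sds <- apply(mat, 2, stats::sd)
  flags <- colnames(mat)[sds == 0]
  r <- diag(1, k); p <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sds[i] == 0 || sds[j] == 0) { rij <- 0; pij <- 1 }
    else {
      rij <- stats::cor(mat[, i], mat[, j])
      tt <- rij * sqrt((n - 2) / max(1e-300, 1 - rij^2))
      pij <- 2 * stats::pt(-abs(tt), n - 2)
    }
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- pij
  }
  dimnames(r) <- dimnames(p) <- list(colnames(mat), colnames(mat))
  structure(list(r = r, p = p, flags = flags, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> Pearson r (7 x 7):\n")
  print(round(x$r, 3))
  if (length(x$flags))
    cat("zero-variance columns:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Vectorized Gaussian Naive Bayes on flattened windows (binary classes).
gnb_fit <- function(X, y, var_floor = 1e-9) {
  fit <- lapply(c(0, 1), function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xi),
         var = pmax(var_floor, apply(Xi, 2, stats::var)),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  names(fit) <- c("0", "1")
  fit
}

gnb_predict <- function(fit, X) {
  ll <- vapply(fit, function(f) {
    rowSums(sweep(sweep(X, 2, f$mu)^2, 2, -2 * f$var, `/`) -
              rep(log(2 * pi * f$var) / 2, each = nrow(X))) + f$logprior
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, 1L)
  as.integer(ll[, 2] > ll[, 1])
}

#' Classifier two-sample test between real and synthetic windows
#'
#' Balances the two pools by downsampling the larger side, trains a Gaussian
#' Naive-Bayes classifier on flattened windows (real = 1, synthetic = 0) on
#' a split fraction, and reports held-out accuracy overall and per label
#' stratum. Accuracy near 0.5 means the sets are indistinguishable to the
#' classifier.
#'
#' @param real,synth [window_set()] objects.
#' @param split Training fraction of each pool.
#' @param seed Seed for downsampling and the split.
#' @return Object of class `c2st_result`: `accuracy` (named vector with
#'   `both`, `stress`, `nonstress`), `n_train`, `n_test`, `seed`.
#' @export
c2st <- function(real, synth, split = 0.5, seed = 1L) {
  n <- min(length(real$labels), length(synth$labels))
  if (n < 4) stop("need at least 4 windows per side", call. = FALSE)
  with_seed(derive_seed(seed, "c2st"), {
    ri <- sample(length(real$labels))[seq_len(n)]
    si <- sample(length(synth$labels))[seq_len(n)]
    X <- rbind(flatten_windows(ws_subset(real, ri)),
               flatten_windows(ws_subset(synth, si)))
    is_real <- c(rep(1L, n), rep(0L, n))
    strat <- c(real$labels[ri], synth$labels[si])
    tr <- c(sample(n)[seq_len(floor(split * n))],
            n + sample(n)[seq_len(floor(split * n))])
    te <- setdiff(seq_len(2L * n), tr)
    fit <- gnb_fit(X[tr, , drop = FALSE], is_real[tr])
    pred <- gnb_predict(fit, X[te, , drop = FALSE])
    acc <- function(sel) if (!any(sel)) NA_real_ else
      mean(pred[sel] == is_real[te][sel])
    structure(list(
      accuracy = c(both = acc(rep(TRUE, length(te))),
                   stress = acc(strat[te] == 1L),
                   nonstress = acc(strat[te] == 0L)),
      n_train = length(tr), n_test = length(te), seed = seed),
      class = "c2st_result")
  })
}

#' @export
print.c2st_result <- function(x, ...) {
  cat(sprintf(
    "<c2st> accuracy both=%.3f stress=%.3f non-stress=%.3f (train %d / test %d)\n",
    x$accuracy[["both"]], x$accuracy[["stress"]], x$accuracy[["nonstress"]],
    x$n_train, x$n_test))
  invisible(x)
}

#' Embed real and synthetic windows in two dimensions
#'
#' PCA is fitted on the real windows only and both sets are projected onto
#' its first two components; per-channel loadings (summed over the 60
#' seconds) are returned. t-SNE embeds the pooled sets jointly (exact
#' algorithm, perplexity 30, fixed seed) and is intended for visualization.
#'
#' @param real,synth [window_set()] objects (>= 3 windows each).
#' @param method `"pca"` or `"tsne"`.
#' @param seed Seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity.
#' @return List with `coords` (data.frame: dim1, dim2, set, label) and, for
#'   PCA, `loadings` (6 x 2 per-channel) and `var_explained`.
#' @export
embed_2d <- function(real, synth, method = c("pca", "tsne"), seed = 1L,
                     perplexity = 30) {
  method <- match.arg(method)
  stopifnot(length(real$labels) >= 3, length(synth$labels) >= 3)
  Xr <- flatten_windows(real); Xs <- flatten_windows(synth)
  meta <- data.frame(
    set = c(rep("real", nrow(Xr)), rep("synthetic", nrow(Xs))),
    label = c(real$labels, synth$labels))
  if (method == "pca") {
    pc <- stats::prcomp(Xr, center = TRUE, scale. = FALSE, rank. = 2L)
    proj <- scale(rbind(Xr, Xs), center = pc$center, scale = FALSE) %*%
      pc$rotation
    load <- t(vapply(seq_len(6L), function(c)
      colSums(pc$rotation[(c - 1L) * 60L + seq_len(60L), , drop = FALSE]),
      numeric(2L)))
    rownames(load) <- e4_signals; colnames(load) <- c("PC1", "PC2")
    ve <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
    list(coords = cbind(data.frame(dim1 = proj[, 1], dim2 = proj[, 2]), meta),
         loadings = load, var_explained = ve)
  } else {
    Y <- tsne_exact(rbind(Xr, Xs), perplexity = perplexity, seed = seed)
    list(coords = cbind(data.frame(dim1 = Y[, 1], dim2 = Y[, 2]), meta))
  }
}

# Exact t-SNE (no tree approximation): suitable for the few hundred windows
# the quality reports operate on.
tsne_exact <- function(X, perplexity = 30, seed = 1L, iters = 300L,
                       lr = 100) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(50L)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sp
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(derive_seed(seed, "tsne"), {
    Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
    gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
    for (it in seq_len(iters)) {
      mult <- if (it <= 100) 4 else 1  # early exaggeration
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (mult * P - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (it <= 50) 0.5 else 0.8
      gains <- pmax(0.01, ifelse(sign(grad) == sign(inc), gains * 0.8,
                                 gains + 0.2))
      inc <- mom * inc - lr * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Compare real and synthetic value densities of one channel
#'
#' Normalized histogram densities over [0,1], per label stratum, for one
#' channel of both window sets. Densities integrate to one. An empty stratum
#' is omitted and flagged.
#'
#' @param real,synth [window_set()] objects.
#' @param signal One of [e4_signals].
#' @param bins Number of histogram bins over [0,1].
#' @return List per stratum (`stress`, `nonstress`) of data frames with
#'   `mid`, `real`, `synth` densities; `omitted` names empty strata.
#' @export
density_compare <- function(real, synth, signal, bins = 50L) {
  if (!signal %in% e4_signals)
    stop_field("signal", paste("must be one of", paste(e4_signals, collapse = ", ")))
  ch <- match(signal, e4_signals)
  br <- seq(0, 1, length.out = bins + 1L)
  dens <- function(v) {
    if (length(v) == 0) return(NULL)
    h <- hist(pmin(1, pmax(0, v)), breaks = br, plot = FALSE)
    h$density
  }
  out <- list(); omitted <- character(0)
  for (st in c(stress = 1L, nonstress = 0L)) {
    nm <- names(which(c(stress = 1L, nonstress = 0L) == st))[1]
    vr <- as.vector(real$windows[real$labels == st, , ch])
    vs <- as.vector(synth$windows[synth$labels == st, , ch])
    if (length(vr) == 0 || length(vs) == 0) { omitted <- c(omitted, nm); next }
    out[[nm]] <- data.frame(mid = (br[-1] + br[-length(br)]) / 2,
                            real = dens(vr), synth = dens(vs))
  }
  out$omitted <- omitted
  out
}

#' Average percentage change between two means
#'
#' `100 * |a - b| / ((a + b) / 2)`: the change between two values relative to
#' their average, symmetric in its arguments (no reference value needed).
#'
#' @param a,b Mean values with `a + b != 0`.
#' @return Percentage change.
#' @export
avg_pct_change <- function(a, b) {
  if (a + b == 0) stop("a + b must be nonzero", call. = FALSE)
  100 * abs(a - b) / ((a + b) / 2)
}
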
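# Conditional GAN over labeled 60 x 6 signal windows.
#
# Generator: per-timestep latent noise + a broadcast one-hot label through
# two stacked LSTM layers and a sigmoid head emitting the six channels per
# second (so any output lies in [0,1]^(60x6) by construction). Discriminator:
# window + broadcast one-hot label through two stacked LSTM layers, last
# hidden state to a sigmoid real/fake score. The generator loss is the
# non-saturating adversarial loss plus a diversity-sensitive penalty that
# rewards output spread relative to latent spread (bounded-ratio form).
# With a privacy spec attached, the discriminator (and only the
# discriminator) trains with per-example clipping and Gaussian noising.

#' Configuration for conditional GAN training
#'
#' @param lambda_div Weight of the diversity penalty in the generator loss.
#' @param learning_rate Adam learning rate for both networks.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param noise_dim Latent dimension per timestep.
#' @param g_width Hidden width of the two generator LSTM layers.
#' @param d_widths Hidden widths of the two discriminator LSTM layers.
#' @param tau Cap of the bounded-ratio diversity term.
#' @param privacy Optional [privacy_spec()]; when present the discriminator
#'   trains privately and `batch_size`, `epochs` and `learning_rate` are
#'   taken from the privacy spec.
#' @param seed Integer seed; training is deterministic given it.
#' @return Object of class `gan_config`.
#' @export
gan_config <- function(lambda_div = 8, learning_rate = 2e-4, batch_size = 64L,
                       epochs = 1600L, noise_dim = 50L, g_width = 128L,
                       d_widths = c(128L, 64L), tau = 1, privacy = NULL,
                       seed = 42L) {
  if (lambda_div < 0) stop_field("lambda_div", "must be non-negative")
  if (epochs < 0) stop_field("epochs", "must be non-negative")
  if (batch_size < 1) stop_field("batch_size", "must be at least 1")
  if (!is.null(privacy)) {
    stopifnot(inherits(privacy, "privacy_spec"))
    batch_size <- privacy$batch_size
    epochs <- privacy$epochs
    learning_rate <- privacy$learning_rate
  }
  structure(list(lambda_div = lambda_div, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), noise_dim = as.integer(noise_dim),
                 g_width = as.integer(g_width), d_widths = as.integer(d_widths),
                 tau = tau, privacy = privacy, seed = as.integer(seed)),
            class = "gan_config")
}

cgan_init_params <- function(config) {
  gw <- config$g_width; d1 <- config$d_widths[1]; d2 <- config$d_widths[2]
  nin <- config$noise_dim + 2L
  G <- c(stats::setNames(lstm_params(nin, gw), c("l1.W", "l1.b")),
         stats::setNames(lstm_params(gw, gw), c("l2.W", "l2.b")),
         stats::setNames(dense_params(gw, 6L), c("head.W", "head.b")))
  D <- c(stats::setNames(lstm_params(8L, d1), c("l1.W", "l1.b")),
         stats::setNames(lstm_params(d1, d2), c("l2.W", "l2.b")),
         stats::setNames(dense_params(d2, 1L), c("head.W", "head.b")))
  list(G = G, D = D)
}

# Sequence-major generator input: rows (t-1)*N + n hold noise[n, , t] plus
# the broadcast one-hot label.
gen_input_matrix <- function(noise, onehot) {
  N <- dim(noise)[1]; T <- dim(noise)[3]
  Z <- matrix(aperm(noise, c(1, 3, 2)), N * T)  # row (t-1)*N + n
  cbind(Z, onehot[rep(seq_len(N), T), , drop = FALSE])
}

# Generator forward: sequence-major input node -> (N*60) x 6 output node.
gen_forward <- function(tp, ids, x, N, gw) {
  h1 <- tp_lstm_seq(tp, x, ids[["l1.W"]], ids[["l1.b"]], gw, N, 60L)
  h2 <- tp_lstm_seq(tp, h1, ids[["l2.W"]], ids[["l2.b"]], gw, N, 60L)
  dense_forward(tp, h2, ids[["head.W"]], ids[["head.b"]], tp_sigmoid)
}

# Discriminator forward: sequence-major (N*60) x 8 node -> N x 1 probs.
disc_forward <- function(tp, ids, x, N, d1, d2) {
  h1 <- tp_lstm_seq(tp, x, ids[["l1.W"]], ids[["l1.b"]], d1, N, 60L)
  h2 <- tp_lstm_seq(tp, h1, ids[["l2.W"]], ids[["l2.b"]], d2, N, 60L)
  last <- tp_rows(tp, h2, 59L * N + seq_len(N))
  dense_forward(tp, last, ids[["head.W"]], ids[["head.b"]], tp_sigmoid)
}

# Sample generator output values (no gradient) for given labels.
gen_sample_values <- function(params, config, labels) {
  N <- length(labels)
  noise <- array(stats::rnorm(N * config$noise_dim * 60L),
                 c(N, config$noise_dim, 60L))
  onehot <- cbind(1 - labels, labels)
  tp <- tape_new()
  ids <- tp_params(tp, params$G)
  x <- tp_const(tp, gen_input_matrix(noise, onehot))
  out <- gen_forward(tp, ids, x, N, config$g_width)
  array(tp_val(tp, out), c(N, 60L, 6L))
}

#' Bounded-ratio diversity penalty
#'
#' The generator-loss regularizer discouraging mode collapse: for two
#' generator draws `w1`, `w2` from latents `z1`, `z2`, returns
#' `-min(tau, ||w1 - w2|| / ||z1 - z2||)`. Larger output spread per unit of
#' latent spread lowers (improves) the penalty, up to the cap `tau`.
#'
#' @param w1,w2 Generated windows (numeric arrays/matrices of equal shape).
#' @param z1,z2 The corresponding latent draws (equal shape, `z1 != z2`).
#' @param tau Ratio cap.
#' @return A scalar penalty in `[-tau, 0]`.
#' @export
diversity_penalty <- function(w1, w2, z1, z2, tau = 1) {
  zdist <- sqrt(sum((z1 - z2)^2))
  if (zdist == 0) stop("z1 and z2 are identical; ratio undefined", call. = FALSE)
  -min(tau, sqrt(sum((w1 - w2)^2)) / zdist)
}

#' Fit a conditional GAN to labeled signal windows
#'
#' Adversarial min-max training with label conditioning in both networks.
#' The discriminator maximizes real/fake discrimination; the generator
#' minimizes the non-saturating adversarial loss plus `lambda_div` times the
#' bounded-ratio diversity penalty evaluated on paired draws within each
#' batch. When `config$privacy` is set, the discriminator's updates (and only
#' those) are privatized by per-example clipping and Gaussian noising with
#' the calibrated noise multiplier.
#'
#' @param windows A [window_set()] with both labels present, values in [0,1].
#' @param config A [gan_config()].
#' @return Object of class `cgan`: generator/discriminator parameters, the
#'   config, a per-epoch loss trace, and a log of which network's updates
#'   carried noise.
#' @export
cgan <- function(windows, config = gan_config()) {
  stopifnot(inherits(windows, "window_set"))
  if (length(unique(windows$labels)) < 2L)
    stop("training windows must contain both labels", call. = FALSE)
  rng <- range(windows$windows)
  if (rng[1] < 0 || rng[2] > 1)
    stop("window values must lie in [0,1]; run the preparation pipeline first",
         call. = FALSE)
  priv <- config$privacy
  dp_on <- !is.null(priv) && is.finite(priv$epsilon)
  with_seed(config$seed, {
    params <- cgan_init_params(config)
    opt_g <- adam_new(params$G, lr = config$learning_rate)
    opt_d <- adam_new(params$D, lr = config$learning_rate)
    N_all <- length(windows$labels)
    bs <- min(config$batch_size, N_all)
    gw <- config$g_width; d1 <- config$d_widths[1]; d2 <- config$d_widths[2]
    losses <- data.frame(epoch = integer(0), d_loss = numeric(0),
                         g_loss = numeric(0))
    if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
      if (dp_on) {
        # Poisson subsampling at rate q matches the accountant's model
        q <- priv$batch_size / N_all
        batches <- list()
        for (s in seq_len(max(1L, round(N_all / priv$batch_size)))) {
          take <- which(stats::runif(N_all) < q)
          if (length(take) > 0) batches[[length(batches) + 1L]] <- take
        }
      } else {
        ord <- sample.int(N_all)
        batches <- split(ord, ceiling(seq_along(ord) / bs))
        batches <- batches[vapply(batches, length, 0L) == bs]
        if (!length(batches)) batches <- list(ord)
      }
      dl <- gl <- 0
      for (idx in batches) {
        n <- length(idx)
        yr <- windows$labels[idx]
        Xr <- windows$windows[idx, , , drop = FALSE]
        # ---- discriminator step
        fake <- gen_sample_values(params, config, yr)
        step <- disc_step(params, config, Xr, fake, yr, opt_d, dp_on, priv,
                          d1, d2)
        params$D <- step$params; opt_d <- step$opt; dl <- dl + step$loss
        # ---- generator step
        step <- gen_step(params, config, yr, opt_g, gw, d1, d2)
        params$G <- step$params; opt_g <- step$opt; gl <- gl + step$loss
      }
      nb <- length(batches)
      if (!is.finite(dl) || !is.finite(gl))
        stop(sprintf("non-finite loss at epoch %d (d=%.3g, g=%.3g)",
                     ep, dl, gl), call. = FALSE)
      losses <- rbind(losses, data.frame(epoch = ep, d_loss = dl / nb,
                                         g_loss = gl / nb))
    }
    structure(list(G = params$G, D = params$D, config = config,
                   losses = losses,
                   noise_log = list(discriminator = dp_on && priv$sigma > 0,
                                    generator = FALSE)),
              class = "cgan")
  })
}

disc_step <- function(params, config, Xr, Xf, yr, opt_d, dp_on, priv, d1, d2) {
  n <- length(yr)
  onehot <- cbind(1 - yr, yr)
  build_loss <- function(tp, ids, Xr_, Xf_, oh) {
    m <- dim(Xr_)[1]
    # stack real above fake inside every timestep block (batch 2m)
    big <- matrix(0, 2L * m * 60L, 6L)
    rows_r <- as.vector(outer(seq_len(m), (seq_len(60L) - 1L) * 2L * m, `+`))
    big[rows_r, ] <- matrix(Xr_, m * 60L)
    big[rows_r + m, ] <- matrix(Xf_, m * 60L)
    ohseq <- rbind(oh, oh)[rep(seq_len(2L * m), 60L), , drop = FALSE]
    p <- disc_forward(tp, ids, tp_const(tp, cbind(big, ohseq)), 2L * m,
                      d1, d2)
    tp_bce(tp, p, c(rep(1, m), rep(0, m)))
  }
  if (!dp_on) {
    tp <- tape_new()
    ids <- tp_params(tp, params$D)
    loss <- build_loss(tp, ids, Xr, Xf, onehot)
    grads <- collect_grads(tp_backward(tp, loss), ids)
    st <- adam_step(opt_d, params$D, grads)
    return(list(params = st$params, opt = st$opt,
                loss = as.numeric(tp_val(tp, loss))))
  }
  # private path: per-example gradients, clip, noise, average
  per_ex <- vector("list", n)
  lval <- 0
  for (i in seq_len(n)) {
    tp <- tape_new()
    ids <- tp_params(tp, params$D)
    loss <- build_loss(tp, ids,
                       Xr[i, , , drop = FALSE], Xf[i, , , drop = FALSE],
                       onehot[i, , drop = FALSE])
    per_ex[[i]] <- collect_grads(tp_backward(tp, loss), ids)
    lval <- lval + as.numeric(tp_val(tp, loss))
  }
  clipped <- clip_per_example(per_ex, priv$clip_norm)
  grads <- dp_aggregate(clipped, priv$sigma, priv$clip_norm, n)
  st <- adam_step(opt_d, params$D, grads)
  list(params = st$params, opt = st$opt, loss = lval / n)
}

gen_step <- function(params, config, yr, opt_g, gw, d1, d2) {
  n <- length(yr)
  noise <- array(stats::rnorm(n * config$noise_dim * 60L),
                 c(n, config$noise_dim, 60L))
  onehot <- cbind(1 - yr, yr)
  tp <- tape_new()
  gids <- tp_params(tp, params$G)
  dids <- tp_params(tp, params$D)
  x <- tp_const(tp, gen_input_matrix(noise, onehot))
  outs <- gen_forward(tp, gids, x, n, gw)
  ohseq <- tp_const(tp, onehot[rep(seq_len(n), 60L), , drop = FALSE])
  p <- disc_forward(tp, dids, tp_cbind(tp, outs, ohseq), n, d1, d2)
  loss <- tp_bce(tp, p, rep(1, n))  # non-saturating: -log D(fake)
  if (config$lambda_div > 0 && n >= 2L) {
    half <- n %/% 2L
    i1 <- seq_len(half); i2 <- half + seq_len(half)
    ridx <- function(i) as.vector(outer(i, (seq_len(60L) - 1L) * n, `+`))
    d <- tp_sub(tp, tp_rows(tp, outs, ridx(i1)), tp_rows(tp, outs, ridx(i2)))
    r <- tp_rowdot(tp, d, d)  # (60*half) x 1, pair p at row (t-1)*half + p
    Msum <- matrix(0, half, 60L * half)
    Msum[cbind(rep(seq_len(half), 60L),
               seq_len(60L * half))] <- 1
    ssq <- tp_mm(tp, tp_const(tp, Msum), r)
    wdist <- tp_sqrt(tp, tp_add(tp, ssq, tp_const(tp, matrix(1e-12, half, 1))))
    zdist <- sqrt(apply((noise[i1, , , drop = FALSE] -
                           noise[i2, , , drop = FALSE])^2, 1, sum))
    ratio_val <- as.vector(tp_val(tp, wdist)) / zdist
    live <- as.numeric(ratio_val < config$tau)  # capped pairs get no gradient
    masked <- tp_colscale(tp, wdist, tp_const(tp, matrix(live / zdist,
                                                         ncol = 1L)))
    pen <- tp_scale(tp, tp_sum(tp, masked), -1 / half)
    capped_part <- -sum(1 - live) * config$tau / half
    loss <- tp_add(tp, loss,
                   tp_add(tp, tp_scale(tp, pen, config$lambda_div),
                          tp_const(tp, matrix(config$lambda_div * capped_part,
                                              1L, 1L))))
  }
  grads <- collect_grads(tp_backward(tp, loss), gids)
  st <- adam_step(opt_g, params$G, grads)
  list(params = st$params, opt = st$opt, loss = as.numeric(tp_val(tp, loss)))
}

#' @export
print.cgan <- function(x, ...) {
  cat(sprintf("<cgan> %s, %d epochs trained, widths G=%d D=%d/%d\n",
              if (!is.null(x$config$privacy) &&
                  is.finite(x$config$privacy$epsilon))
                sprintf("DP (epsilon=%.3g)", x$config$privacy$epsilon)
              else "non-private",
              nrow(x$losses), x$config$g_width, x$config$d_widths[1],
              x$config$d_widths[2]))
  if (nrow(x$losses) > 0)
    cat(sprintf("  final losses: D=%.4f G=%.4f\n",
                utils::tail(x$losses$d_loss, 1),
                utils::tail(x$losses$g_loss, 1)))
  invisible(x)
}

#' @export
summary.cgan <- function(object, ...) {
  cat("Conditional GAN over 60 s x 6 channel stress-signal windows\n")
  print(object)
  cat(sprintf("  lambda_div=%.1f lr=%.2g batch=%d noise_dim=%d seed=%d\n",
              object$config$lambda_div, object$config$learning_rate,
              object$config$batch_size, object$config$noise_dim,
              object$config$seed))
  invisible(object)
}

#' Plot the training-loss trace of a fitted conditional GAN
#' @param x A `cgan` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cgan <- function(x, ...) {
  if (nrow(x$losses) == 0) stop("no training epochs to plot", call. = FALSE)
  graphics::matplot(x$losses$epoch, cbind(x$losses$d_loss, x$losses$g_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("discriminator", "generator"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Synthesize subject-sized cohorts from a fitted generator
#'
#' Per synthetic subject, samples one subject-duration of windows
#' (`subject_minutes` one-minute windows) with labels drawn to realize the
#' target stress share exactly (`round(stress_share * n_windows)` stress
#' windows, shuffled), then generates windows conditioned on those labels.
#'
#' @param state A fitted (or initialized) `cgan`.
#' @param n_subjects Number of synthetic subjects (>= 1).
#' @param stress_share Target share of stress windows.
#' @param subject_minutes Minutes of data per subject (36 matches a typical
#'   study session).
#' @param seed Seed for noise and label shuffling.
#' @return A [window_set()] of `n_subjects * subject_minutes` windows with
#'   subject ids `SYN001`, `SYN002`, ...
#' @export
synthesize_subjects <- function(state, n_subjects, stress_share = 0.30,
                                subject_minutes = 36L, seed = 1L) {
  stopifnot(inherits(state, "cgan"))
  if (n_subjects < 1) stop_field("n_subjects", "must be at least 1")
  wps <- as.integer(ceiling(60 * subject_minutes / 60))
  n_stress <- as.integer(round(stress_share * wps))
  with_seed(derive_seed(seed, "synth"), {
    sets <- lapply(seq_len(n_subjects), function(s) {
      labs <- sample(c(rep(1L, n_stress), rep(0L, wps - n_stress)))
      arr <- gen_sample_values(list(G = state$G), state$config, labs)
      window_set(arr, labs, rep(sprintf("SYN%03d", s), wps), 60L)
    })
    do.call(c, sets)
  })
}

#' Simulate labeled windows from a fitted conditional GAN
#'
#' `simulate()` draws `nsim` synthetic subjects via [synthesize_subjects()].
#' @param object A `cgan`.
#' @param nsim Number of synthetic subjects.
#' @param seed Seed passed to the sampler.
#' @param ... Further arguments to [synthesize_subjects()].
#' @export
simulate.cgan <- function(object, nsim = 1, seed = 1L, ...) {
  synthesize_subjects(object, n_subjects = nsim, seed = seed, ...)
}
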
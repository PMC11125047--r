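# Stress classifiers over 6 x 210 spectral features: a 1-D CNN, a hybrid
# CNN-LSTM, and a small transformer (TSCT). All three share the training
# loop (weighted binary cross-entropy, Adam, optional DP-SGD path via the dp
# module) and the evaluation contract (0.5 threshold, confusion-derived
# metrics with explicit degenerate rules).

#' Configuration for a stress classifier
#'
#' @param kind `"cnn"`, `"cnn_lstm"` or `"tsct"`.
#' @param epochs Training epochs; defaults per kind (cnn 10, cnn_lstm 20,
#'   tsct 110).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param class_weights Weight examples by inverse class frequency
#'   (normalized to mean 1).
#' @param privacy Optional [privacy_spec()] for DP-SGD training (per-example
#'   clipping + calibrated Gaussian noise); with `epsilon = Inf` training is
#'   non-private with a notice.
#' @param conv_widths,kernel,pool CNN convolution stack (1-D over the 210
#'   frequency axis, 6 input channels).
#' @param dense_width Width of the dense layer before the output.
#' @param lstm_widths Recurrent widths of the hybrid model, inserted between
#'   the convolutional part and the dense layers.
#' @param d_model,n_heads,n_blocks,ffn_width Transformer dimensions (the
#'   6 x 210 input is treated as a 6-token sequence).
#' @param seed Integer seed.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("cnn", "cnn_lstm", "tsct"),
                              epochs = NULL, batch_size = 50L,
                              learning_rate = 1e-3, class_weights = TRUE,
                              privacy = NULL,
                              conv_widths = c(32L, 64L, 128L), kernel = 5L,
                              pool = 2L, dense_width = 128L,
                              lstm_widths = c(128L, 64L), d_model = 64L,
                              n_heads = 4L, n_blocks = 2L, ffn_width = 128L,
                              seed = 42L) {
  kind <- match.arg(kind)
  epochs <- as.integer(epochs %||%
                         switch(kind, cnn = 10L, cnn_lstm = 20L, tsct = 110L))
  if (epochs < 1) stop_field("epochs", "must be at least 1")
  if (batch_size < 1) stop_field("batch_size", "must be at least 1")
  structure(list(kind = kind, epochs = epochs,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, class_weights = class_weights,
                 privacy = privacy, conv_widths = as.integer(conv_widths),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dense_width = as.integer(dense_width),
                 lstm_widths = as.integer(lstm_widths),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_blocks = as.integer(n_blocks),
                 ffn_width = as.integer(ffn_width), seed = as.integer(seed)),
            class = "classifier_config")
}

clf_init_params <- function(cfg, n_points = 210L) {
  p <- list()
  if (cfg$kind %in% c("cnn", "cnn_lstm")) {
    cin <- 6L
    L <- n_points
    for (b in seq_along(cfg$conv_widths)) {
      w <- cfg$conv_widths[b]
      p[[sprintf("conv%d.W", b)]] <- glorot(cfg$kernel * cin, w)
      p[[sprintf("conv%d.b", b)]] <- matrix(0, 1L, w)
      cin <- w
      L <- ((L - cfg$kernel) + 1L) %/% cfg$pool
    }
    if (cfg$kind == "cnn_lstm") {
      lp <- lstm_params(cin, cfg$lstm_widths[1])
      p[["lstm1.W"]] <- lp$W; p[["lstm1.b"]] <- lp$b
      lp <- lstm_params(cfg$lstm_widths[1], cfg$lstm_widths[2])
      p[["lstm2.W"]] <- lp$W; p[["lstm2.b"]] <- lp$b
      flat_in <- cfg$lstm_widths[2]
    } else {
      flat_in <- L * cin
    }
    dp1 <- dense_params(flat_in, cfg$dense_width)
    p[["dense.W"]] <- dp1$W; p[["dense.b"]] <- dp1$b
    dp2 <- dense_params(cfg$dense_width, 1L)
    p[["out.W"]] <- dp2$W; p[["out.b"]] <- dp2$b
    attr(p, "seq_len_out") <- L
  } else {
    d <- cfg$d_model; dh <- d %/% cfg$n_heads
    pr <- dense_params(n_points, d)
    p[["proj.W"]] <- pr$W; p[["proj.b"]] <- pr$b
    p[["pos"]] <- matrix(stats::rnorm(6L * d, 0, 0.02), 6L, d)
    for (b in seq_len(cfg$n_blocks)) {
      for (h in seq_len(cfg$n_heads)) {
        p[[sprintf("b%d.h%d.Wq", b, h)]] <- glorot(d, dh)
        p[[sprintf("b%d.h%d.Wk", b, h)]] <- glorot(d, dh)
        p[[sprintf("b%d.h%d.Wv", b, h)]] <- glorot(d, dh)
      }
      p[[sprintf("b%d.Wo", b)]] <- glorot(d, d)
      p[[sprintf("b%d.ln1.g", b)]] <- matrix(1, 1L, d)
      p[[sprintf("b%d.ln1.b", b)]] <- matrix(0, 1L, d)
      f1 <- dense_params(d, cfg$ffn_width)
      p[[sprintf("b%d.ffn1.W", b)]] <- f1$W
      p[[sprintf("b%d.ffn1.b", b)]] <- f1$b
      f2 <- dense_params(cfg$ffn_width, d)
      p[[sprintf("b%d.ffn2.W", b)]] <- f2$W
      p[[sprintf("b%d.ffn2.b", b)]] <- f2$b
      p[[sprintf("b%d.ln2.g", b)]] <- matrix(1, 1L, d)
      p[[sprintf("b%d.ln2.b", b)]] <- matrix(0, 1L, d)
    }
    dp2 <- dense_params(d, 1L)
    p[["out.W"]] <- dp2$W; p[["out.b"]] <- dp2$b
  }
  p
}

# features: N x 6 x 210 array -> sequence-major (N*210) x 6 matrix
feat_to_seq <- function(feats) {
  N <- dim(feats)[1]; L <- dim(feats)[3]
  m <- matrix(0, N * L, 6L)
  for (c in seq_len(6L)) m[, c] <- as.vector(feats[, c, ])
  m
}

clf_forward <- function(tp, ids, feats, cfg) {
  N <- dim(feats)[1]; n_points <- dim(feats)[3]
  if (cfg$kind %in% c("cnn", "cnn_lstm")) {
    x <- tp_const(tp, feat_to_seq(feats))
    L <- n_points; cin <- 6L
    for (b in seq_along(cfg$conv_widths)) {
      x <- tp_im2col(tp, x, N, L, cfg$kernel)
      x <- tp_relu(tp, tp_add(tp, tp_mm(tp, x, ids[[sprintf("conv%d.W", b)]]),
                              ids[[sprintf("conv%d.b", b)]]))
      L <- L - cfg$kernel + 1L
      x <- tp_maxpool_seq(tp, x, N, L, cfg$pool)
      L <- L %/% cfg$pool
      cin <- cfg$conv_widths[b]
    }
    if (cfg$kind == "cnn_lstm") {
      h1 <- tp_lstm_seq(tp, x, ids[["lstm1.W"]], ids[["lstm1.b"]],
                        cfg$lstm_widths[1], N, L)
      h2 <- tp_lstm_seq(tp, h1, ids[["lstm2.W"]], ids[["lstm2.b"]],
                        cfg$lstm_widths[2], N, L)
      flat <- tp_rows(tp, h2, (L - 1L) * N + seq_len(N))
    } else {
      flat <- tp_seqflatten(tp, x, N, L)
    }
    hidden <- dense_forward(tp, flat, ids[["dense.W"]], ids[["dense.b"]],
                            tp_relu)
    dense_forward(tp, hidden, ids[["out.W"]], ids[["out.b"]], tp_sigmoid)
  } else {
    d <- cfg$d_model; dh <- d %/% cfg$n_heads
    toks <- lapply(seq_len(6L), function(c) {
      x <- tp_const(tp, matrix(feats[, c, ], nrow = N))
      x <- tp_add(tp, tp_mm(tp, x, ids[["proj.W"]]), ids[["proj.b"]])
      tp_add(tp, x, tp_rows(tp, ids[["pos"]], c))
    })
    for (b in seq_len(cfg$n_blocks)) {
      heads_out <- vector("list", 6L)
      for (i in seq_len(6L)) heads_out[[i]] <- vector("list", cfg$n_heads)
      for (h in seq_len(cfg$n_heads)) {
        Q <- lapply(toks, function(t)
          tp_mm(tp, t, ids[[sprintf("b%d.h%d.Wq", b, h)]]))
        K <- lapply(toks, function(t)
          tp_mm(tp, t, ids[[sprintf("b%d.h%d.Wk", b, h)]]))
        V <- lapply(toks, function(t)
          tp_mm(tp, t, ids[[sprintf("b%d.h%d.Wv", b, h)]]))
        for (i in seq_len(6L)) {
          sc <- lapply(seq_len(6L), function(j)
            tp_scale(tp, tp_rowdot(tp, Q[[i]], K[[j]]), 1 / sqrt(dh)))
          alpha <- tp_softmax_rows(tp, do.call(tp_cbind, c(list(tp), sc)))
          ctx <- NULL
          for (j in seq_len(6L)) {
            term <- tp_colscale(tp, V[[j]], tp_cols(tp, alpha, j))
            ctx <- if (is.null(ctx)) term else tp_add(tp, ctx, term)
          }
          heads_out[[i]][[h]] <- ctx
        }
      }
      toks <- lapply(seq_len(6L), function(i) {
        att <- tp_mm(tp, do.call(tp_cbind, c(list(tp), heads_out[[i]])),
                     ids[[sprintf("b%d.Wo", b)]])
        x <- tp_layernorm(tp, tp_add(tp, toks[[i]], att),
                          ids[[sprintf("b%d.ln1.g", b)]],
                          ids[[sprintf("b%d.ln1.b", b)]])
        ff <- dense_forward(tp,
                            dense_forward(tp, x, ids[[sprintf("b%d.ffn1.W", b)]],
                                          ids[[sprintf("b%d.ffn1.b", b)]],
                                          tp_relu),
                            ids[[sprintf("b%d.ffn2.W", b)]],
                            ids[[sprintf("b%d.ffn2.b", b)]])
        tp_layernorm(tp, tp_add(tp, x, ff),
                     ids[[sprintf("b%d.ln2.g", b)]],
                     ids[[sprintf("b%d.ln2.b", b)]])
      })
    }
    pooled <- toks[[1]]
    for (i in 2:6) pooled <- tp_add(tp, pooled, toks[[i]])
    pooled <- tp_scale(tp, pooled, 1 / 6)
    dense_forward(tp, pooled, ids[["out.W"]], ids[["out.b"]], tp_sigmoid)
  }
}

#' Train a stress classifier on spectral features
#'
#' Fits the configured architecture with weighted binary cross-entropy and
#' Adam. With a finite-epsilon [privacy_spec()] in the config, updates use
#' per-example gradient clipping and calibrated Gaussian noise (DP-SGD);
#' training is deterministic given the seed.
#'
#' @param features A [featurize_windows()] `spectrum_set` with both classes.
#' @param config A [classifier_config()].
#' @return Object of class `stress_classifier`.
#' @export
stress_classifier <- function(features, config = classifier_config("cnn")) {
  stopifnot(inherits(features, "spectrum_set"))
  y <- features$labels
  if (length(unique(y)) < 2L)
    stop("training features must contain both classes", call. = FALSE)
  priv <- config$privacy
  dp_on <- !is.null(priv) && is.finite(priv$epsilon)
  if (!is.null(priv) && !is.finite(priv$epsilon))
    message("privacy spec has epsilon = Inf; training non-privately")
  # inverse class frequency, normalized to mean 1
  w <- if (config$class_weights) {
    raw <- 1 / (c(mean(y == 0), mean(y == 1))[y + 1L])
    raw / mean(raw)
  } else rep(1, length(y))
  with_seed(config$seed, {
    params <- clf_init_params(config, dim(features$features)[3])
    opt <- adam_new(params, lr = config$learning_rate)
    N_all <- length(y)
    bs <- min(if (dp_on) priv$batch_size else config$batch_size, N_all)
    trace <- numeric(0)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N_all)
      batches <- split(ord, ceiling(seq_along(ord) / bs))
      eploss <- 0
      for (idx in batches) {
        feats <- features$features[idx, , , drop = FALSE]
        if (!dp_on) {
          tp <- tape_new()
          ids <- tp_params(tp, params)
          pnode <- clf_forward(tp, ids, feats, config)
          loss <- tp_bce(tp, pnode, y[idx], w[idx])
          grads <- collect_grads(tp_backward(tp, loss), ids)
          st <- adam_step(opt, params, grads)
          eploss <- eploss + as.numeric(tp_val(tp, loss))
        } else {
          per_ex <- vector("list", length(idx))
          lsum <- 0
          for (i in seq_along(idx)) {
            tp <- tape_new()
            ids <- tp_params(tp, params)
            pnode <- clf_forward(tp, ids,
                                 feats[i, , , drop = FALSE], config)
            loss <- tp_bce(tp, pnode, y[idx[i]], w[idx[i]])
            per_ex[[i]] <- collect_grads(tp_backward(tp, loss), ids)
            lsum <- lsum + as.numeric(tp_val(tp, loss))
          }
          clipped <- clip_per_example(per_ex, priv$clip_norm)
          grads <- dp_aggregate(clipped, priv$sigma, priv$clip_norm,
                                length(idx))
          st <- adam_step(opt, params, grads)
          eploss <- eploss + lsum / length(idx)
        }
        opt <- st$opt; params <- st$params
      }
      if (!is.finite(eploss))
        stop(sprintf("non-finite loss at epoch %d", ep), call. = FALSE)
      trace <- c(trace, eploss / length(batches))
    }
    structure(list(params = params, config = config, loss_trace = trace,
                   architecture = clf_architecture(config),
                   private = dp_on),
              class = "stress_classifier")
  })
}

clf_architecture <- function(cfg) {
  switch(cfg$kind,
    cnn = list(kind = "cnn", conv_widths = cfg$conv_widths,
               kernel = cfg$kernel, dense = cfg$dense_width),
    cnn_lstm = list(kind = "cnn_lstm", conv_widths = cfg$conv_widths,
                    kernel = cfg$kernel, lstm_widths = cfg$lstm_widths,
                    dense = cfg$dense_width),
    tsct = list(kind = "tsct", d_model = cfg$d_model, n_heads = cfg$n_heads,
                n_blocks = cfg$n_blocks, ffn = cfg$ffn_width))
}

#' @export
print.stress_classifier <- function(x, ...) {
  cat(sprintf("<stress_classifier> %s%s, %d epochs trained\n",
              x$config$kind, if (x$private) " (DP)" else "",
              length(x$loss_trace)))
  invisible(x)
}

#' Predicted stress probabilities or classes
#'
#' @param object A fitted [stress_classifier()].
#' @param features A `spectrum_set`.
#' @param type `"prob"` or `"class"` (0.5 threshold).
#' @param ... Unused.
#' @export
predict.stress_classifier <- function(object, features,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  tp <- tape_new()
  ids <- tp_params(tp, object$params)
  p <- tp_val(tp, clf_forward(tp, ids, features$features, object$config))
  p <- as.vector(p)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Metrics from confusion counts
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), F1 = 2PR/(P+R), accuracy.
#' Zero-denominator cases are reported as 0 and flagged.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return Object of class `stress_metrics`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  flags <- character(0)
  prec <- if (tp + fp == 0) { flags <- c(flags, "precision_undefined"); 0 }
    else tp / (tp + fp)
  rec <- if (tp + fn == 0) { flags <- c(flags, "recall_undefined"); 0 }
    else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  structure(list(precision = prec, recall = rec, f1 = f1,
                 accuracy = (tp + tn) / max(1, tp + fp + fn + tn),
                 tp = tp, fp = fp, fn = fn, tn = tn, flags = flags),
            class = "stress_metrics")
}

#' @export
print.stress_metrics <- function(x, ...) {
  cat(sprintf("P=%.4f R=%.4f F1=%.4f acc=%.4f (TP=%d FP=%d FN=%d TN=%d)\n",
              x$precision, x$recall, x$f1, x$accuracy, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Evaluate a classifier on labeled spectral features
#'
#' Hard predictions at the 0.5 threshold; confusion counts and the derived
#' precision/recall/F1/accuracy.
#'
#' @param model A fitted [stress_classifier()].
#' @param features A `spectrum_set` with labels.
#' @return A [confusion_metrics()] object.
#' @export
evaluate_classifier <- function(model, features) {
  if (length(features$labels) == 0) stop("empty feature set", call. = FALSE)
  pred <- predict(model, features, type = "class")
  y <- features$labels
  confusion_metrics(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
                    fn = sum(pred == 0 & y == 1), tn = sum(pred == 0 & y == 0))
}
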
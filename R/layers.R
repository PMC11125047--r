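# Network building blocks on top of the autodiff tape: parameter
# initialization, dense and LSTM layers, and a hand-rolled Adam optimizer.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# LSTM parameters: one fused weight matrix (in+h) x 4h, gate order i,f,o,g;
# forget-gate bias initialized to 1.
lstm_params <- function(n_in, n_hidden) {
  b <- matrix(0, 1L, 4L * n_hidden)
  b[1L, n_hidden + seq_len(n_hidden)] <- 1
  list(W = glorot(n_in + n_hidden, 4L * n_hidden), b = b)
}

dense_params <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out), b = matrix(0, 1L, n_out))
}

# Put a flat named list of matrices onto the tape; returns node ids with the
# same names.
tp_params <- function(tp, params) {
  lapply(params, function(p) tp_param(tp, p))
}

dense_forward <- function(tp, x, Wid, bid, act = NULL) {
  y <- tp_add(tp, tp_mm(tp, x, Wid), bid)
  if (is.null(act)) y else act(tp, y)
}

# Adam optimizer state over a flat named list of parameter matrices.
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Collect gradients for named parameter node ids from a backward pass.
collect_grads <- function(grads, ids) {
  out <- lapply(ids, function(id) grads[[id]])
  out[vapply(out, is.null, TRUE)] <- NULL
  out
}
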
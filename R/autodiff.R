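# Minimal reverse-mode automatic differentiation over matrix operations.
#
# A tape records nodes (value + parent ids + backward closure); backward()
# walks the tape in reverse, accumulating gradients. All network training in
# the package (conditional GAN, classifiers, DP variants) runs on this
# engine; its gradients are checked against central finite differences in the
# test suite.
#
# Conventions: node values are numeric matrices. Batched sequences use the
# "sequence-major" layout (N*L) x C with row index (p-1)*N + n for position p
# of batch element n.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$back <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tp, val, parents = integer(0), back = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {           # grow storage geometrically
    length(tp$vals) <- 2L * n
    length(tp$parents) <- 2L * n
    length(tp$back) <- 2L * n
  }
  tp$vals[[n]] <- val
  tp$parents[[n]] <- parents
  if (!is.null(back)) tp$back[[n]] <- back
  tp$n <- n
  n
}

tp_val <- function(tp, id) {
  force(id)  # nested op calls append to the tape before we read it
  tp$vals[[id]]
}

tp_const <- function(tp, v) tp_node(tp, v)
tp_param <- tp_const

# y = a %*% b
tp_mm <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_node(tp, A %*% B, c(a, b),
          function(g) list(g %*% t(B), crossprod(A, g)))
}

# y = a + b; b may be a 1 x k row vector broadcast over rows of a
tp_add <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  if (is.matrix(B) && nrow(B) == 1L && nrow(A) > 1L) {
    val <- sweep(A, 2, as.vector(B), `+`)
    tp_node(tp, val, c(a, b),
            function(g) list(g, matrix(colSums(g), 1L)))
  } else {
    tp_node(tp, A + B, c(a, b), function(g) list(g, g))
  }
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_node(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g) list(g, -g))
}

# elementwise product (equal shapes)
tp_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_node(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# y = k * a for scalar constant k
tp_scale <- function(tp, a, k) {
  force(a)
  tp_node(tp, k * tp$vals[[a]], a, function(g) list(k * g))
}

tp_sigmoid <- function(tp, a) {
  force(a)
  s <- 1 / (1 + exp(-tp$vals[[a]]))
  tp_node(tp, s, a, function(g) list(g * s * (1 - s)))
}

tp_tanh <- function(tp, a) {
  force(a)
  s <- tanh(tp$vals[[a]])
  tp_node(tp, s, a, function(g) list(g * (1 - s^2)))
}

tp_relu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  m <- A > 0
  tp_node(tp, A * m, a, function(g) list(g * m))
}

# concatenate columns
tp_cbind <- function(tp, ...) {
  ids <- c(...)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  ks <- vapply(vals, ncol, 0L)
  ends <- cumsum(ks)
  tp_node(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(j)
      g[, (ends[j] - ks[j] + 1L):ends[j], drop = FALSE])
  })
}

# select columns
tp_cols <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nc <- ncol(A)
  tp_node(tp, A[, idx, drop = FALSE], a, function(g) {
    gA <- matrix(0, nrow(g), nc)
    gA[, idx] <- g
    list(gA)
  })
}

# select rows
tp_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A)
  tp_node(tp, A[idx, , drop = FALSE], a, function(g) {
    gA <- matrix(0, nr, ncol(g))
    gA[idx, ] <- gA[idx, ] + g
    list(gA)
  })
}

# scalar mean of all entries -> 1x1
tp_mean <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  n <- length(A)
  tp_node(tp, matrix(mean(A), 1L, 1L), a, function(g)
    list(matrix(as.numeric(g) / n, nrow(A), ncol(A))))
}

tp_sum <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_node(tp, matrix(sum(A), 1L, 1L), a, function(g)
    list(matrix(as.numeric(g), nrow(A), ncol(A))))
}

tp_sqrt <- function(tp, a) {
  force(a)
  s <- sqrt(tp$vals[[a]])
  tp_node(tp, s, a, function(g) list(g / (2 * s)))
}

# scale each row of v by the column vector alpha (N x 1)
tp_colscale <- function(tp, v, alpha) {
  force(v); force(alpha)
  V <- tp$vals[[v]]; A <- as.vector(tp$vals[[alpha]])
  tp_node(tp, V * A, c(v, alpha), function(g)
    list(g * A, matrix(rowSums(g * V), ncol = 1L)))
}

# row-wise inner product: N x 1 of rowSums(a * b)
tp_rowdot <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_node(tp, matrix(rowSums(A * B), ncol = 1L), c(a, b), function(g) {
    gv <- as.vector(g)
    list(A * 0 + gv * B, B * 0 + gv * A)
  })
}

# softmax over each row
tp_softmax_rows <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  m <- A - apply(A, 1, max)
  e <- exp(m)
  s <- e / rowSums(e)
  tp_node(tp, s, a, function(g)
    list((g - rowSums(g * s)) * s))
}

# layer normalization over rows with learned gain/bias (1 x k each)
tp_layernorm <- function(tp, a, gamma, beta, eps = 1e-5) {
  force(a); force(gamma); force(beta)
  A <- tp$vals[[a]]; G <- as.vector(tp$vals[[gamma]])
  k <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- sweep(xhat * rep(G, each = nrow(A)), 2, as.vector(tp$vals[[beta]]), `+`)
  tp_node(tp, val, c(a, gamma, beta), function(g) {
    gxhat <- g * rep(G, each = nrow(g))
    gA <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(gA,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# weighted binary cross-entropy on probabilities p (N x 1), labels y, weights w
tp_bce <- function(tp, p, y, w = NULL) {
  force(p)
  P <- pmin(1 - 1e-7, pmax(1e-7, tp$vals[[p]]))
  y <- as.vector(y)
  n <- length(y)
  w <- if (is.null(w)) rep(1, n) else as.vector(w)
  val <- -mean(w * (y * log(P) + (1 - y) * log(1 - P)))
  tp_node(tp, matrix(val, 1L, 1L), p, function(g)
    list(matrix(as.numeric(g) * w * (-(y / P) + (1 - y) / (1 - P)) / n,
                ncol = 1L)))
}

# im2col for 1-D convolution over sequence-major input ((N*L) x Cin):
# output ((N*Lout) x (K*Cin)); column block c holds the K kernel taps.
tp_im2col <- function(tp, a, N, L, K, stride = 1L) {
  force(a)
  A <- tp$vals[[a]]
  Cin <- ncol(A)
  Lout <- (L - K) %/% stride + 1L
  big <- matrix(0, N * Lout, K * Cin)
  for (p in seq_len(Lout)) {
    rows_in <- rep(((p - 1L) * stride + seq_len(K)) - 1L, each = N) * N +
      seq_len(N)
    big[(p - 1L) * N + seq_len(N), ] <- matrix(A[rows_in, ], N)
  }
  tp_node(tp, big, a, function(g) {
    gA <- matrix(0, nrow(A), Cin)
    for (p in seq_len(Lout)) {
      gp <- g[(p - 1L) * N + seq_len(N), , drop = FALSE]
      for (k in seq_len(K)) {
        rows_in <- ((p - 1L) * stride + k - 1L) * N + seq_len(N)
        # column (c-1)*K + k of the im2col matrix holds channel c, tap k
        gA[rows_in, ] <- gA[rows_in, ] +
          gp[, (seq_len(Cin) - 1L) * K + k, drop = FALSE]
      }
    }
    list(gA)
  })
}

# max-pool along the sequence axis of a sequence-major matrix
tp_maxpool_seq <- function(tp, a, N, L, pool = 2L) {
  force(a)
  A <- tp$vals[[a]]
  Lp <- L %/% pool
  C <- ncol(A)
  val <- matrix(-Inf, N * Lp, C)
  arg <- matrix(1L, N * Lp, C)
  for (q in seq_len(Lp)) {
    out_rows <- (q - 1L) * N + seq_len(N)
    vo <- val[out_rows, , drop = FALSE]
    ao <- arg[out_rows, , drop = FALSE]
    for (j in seq_len(pool)) {
      rows_in <- ((q - 1L) * pool + j - 1L) * N + seq_len(N)
      m <- A[rows_in, , drop = FALSE]
      upd <- m > vo
      vo[upd] <- m[upd]
      ao[upd] <- j
    }
    val[out_rows, ] <- vo
    arg[out_rows, ] <- ao
  }
  tp_node(tp, val, a, function(g) {
    gA <- matrix(0, nrow(A), C)
    for (q in seq_len(Lp)) {
      out_rows <- (q - 1L) * N + seq_len(N)
      go <- g[out_rows, , drop = FALSE]
      ao <- arg[out_rows, , drop = FALSE]
      for (j in seq_len(pool)) {
        rows_in <- ((q - 1L) * pool + j - 1L) * N + seq_len(N)
        gi <- gA[rows_in, , drop = FALSE]
        sel <- ao == j
        gi[sel] <- gi[sel] + go[sel]
        gA[rows_in, ] <- gi
      }
    }
    list(gA)
  })
}

# Fused LSTM layer over a sequence-major input ((N*T) x n_in): forward loop
# with cached gates, hand-derived backpropagation-through-time. Gate order
# i, f, o, g in the fused weight matrix W ((n_in+h) x 4h). Returns the full
# hidden sequence ((N*T) x h).
tp_lstm_seq <- function(tp, x, W, b, n_hidden, N, T) {
  force(x); force(W); force(b)
  X <- tp$vals[[x]]; Wv <- tp$vals[[W]]; bv <- as.vector(tp$vals[[b]])
  n_in <- ncol(X)
  h <- n_hidden
  i1 <- seq_len(h)
  H <- matrix(0, N * T, h)
  cache <- vector("list", T)
  hp <- matrix(0, N, h); cp <- matrix(0, N, h)
  for (t in seq_len(T)) {
    rows <- (t - 1L) * N + seq_len(N)
    xh <- cbind(X[rows, , drop = FALSE], hp)
    z <- sweep(xh %*% Wv, 2, bv, `+`)
    gi <- 1 / (1 + exp(-z[, i1, drop = FALSE]))
    gf <- 1 / (1 + exp(-z[, h + i1, drop = FALSE]))
    go <- 1 / (1 + exp(-z[, 2L * h + i1, drop = FALSE]))
    gg <- tanh(z[, 3L * h + i1, drop = FALSE])
    cn <- gf * cp + gi * gg
    tc <- tanh(cn)
    hn <- go * tc
    cache[[t]] <- list(xh = xh, gi = gi, gf = gf, go = go, gg = gg,
                       cp = cp, tc = tc)
    H[rows, ] <- hn
    hp <- hn; cp <- cn
  }
  tp_node(tp, H, c(x, W, b), function(g) {
    gX <- matrix(0, nrow(X), n_in)
    gW <- matrix(0, nrow(Wv), ncol(Wv))
    gb <- matrix(0, 1L, 4L * h)
    dh_next <- matrix(0, N, h)
    dc_next <- matrix(0, N, h)
    for (t in rev(seq_len(T))) {
      cc <- cache[[t]]
      rows <- (t - 1L) * N + seq_len(N)
      dh <- g[rows, , drop = FALSE] + dh_next
      dc <- dc_next + dh * cc$go * (1 - cc$tc^2)
      do_ <- dh * cc$tc
      di <- dc * cc$gg
      df <- dc * cc$cp
      dg <- dc * cc$gi
      dc_next <- dc * cc$gf
      dz <- cbind(di * cc$gi * (1 - cc$gi), df * cc$gf * (1 - cc$gf),
                  do_ * cc$go * (1 - cc$go), dg * (1 - cc$gg^2))
      gW <- gW + crossprod(cc$xh, dz)
      gb <- gb + colSums(dz)
      dxh <- dz %*% t(Wv)
      gX[rows, ] <- dxh[, seq_len(n_in), drop = FALSE]
      dh_next <- dxh[, n_in + seq_len(h), drop = FALSE]
    }
    list(gX, gW, gb)
  })
}

# flatten a sequence-major matrix ((N*L) x C) to N x (L*C), channel-major
# column blocks: out[n, (c-1)*L + p] = a[(p-1)*N + n, c]
tp_seqflatten <- function(tp, a, N, L) {
  force(a)
  A <- tp$vals[[a]]
  C <- ncol(A)
  # out flat position n + ((c-1)*L + p - 1)*N  <-  a flat position
  # (p-1)*N + n + (c-1)*N*L ; build the permutation once
  p <- rep(rep(seq_len(L), each = N), times = C)
  n <- rep(seq_len(N), times = L * C)
  cc <- rep(seq_len(C), each = N * L)
  src <- (p - 1L) * N + n + (cc - 1L) * N * L
  val <- matrix(as.vector(A)[src], N, L * C)
  tp_node(tp, val, a, function(g) {
    gA <- numeric(length(A))
    gA[src] <- as.vector(g)
    list(matrix(gA, nrow(A), C))
  })
}

# Reverse pass from scalar node `loss`; returns list of gradients per node id.
tp_backward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  grads[[loss]] <- matrix(1, 1L, 1L)
  for (i in loss:1L) {
    g <- grads[[i]]
    if (is.null(g)) next
    bk <- tp$back[[i]]
    if (is.null(bk)) next
    pg <- bk(g)
    ps <- tp$parents[[i]]
    for (j in seq_along(ps)) {
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}
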
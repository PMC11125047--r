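test_that("correlation matrices reproduce closed-form Pearson r and p", {
  ws <- toy_window_set(8)
  rep <- correlation_with_p(ws)
  expect_equal(dim(rep$r), c(7L, 7L))
  expect_equal(unname(diag(rep$r)), rep(1, 7))
  expect_equal(rep$r, t(rep$r))
  expect_true(all(abs(rep$r) <= 1) && all(rep$p >= 0 & rep$p <= 1))
  # direct-sum closed form oracle on random columns
  pearson <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  mat <- cbind(matrix(aperm(ws$windows, c(2, 1, 3)), 8 * 60),
               rep(ws$labels, each = 60))
  for (pair in list(c(1, 2), c(5, 7), c(3, 6))) {
    expect_equal(rep$r[pair[1], pair[2]],
                 pearson(mat[, pair[1]], mat[, pair[2]]), tolerance = 1e-10)
  }
  # hand-checkable perfect correlations
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, c(2, 4, 6, 8)), 1)
  expect_equal(pearson(x, c(8, 6, 4, 2)), -1)
})

test_that("prepared fixtures recover the stress-physiology correlation signs", {
  rep <- correlation_with_p(small_windows(10, seed = 31))
  expect_gt(rep$r["EDA", "Label"], 0)
  expect_lt(rep$r["TEMP", "Label"], 0)
  expect_lt(rep$p["EDA", "Label"], 0.01)
})

test_that("degenerate zero-variance columns are flagged, not propagated", {
  ws <- toy_window_set(8)
  ws$windows[, , 4] <- 0.5
  rep <- correlation_with_p(ws)
  expect_true("BVP" %in% rep$flags)
  expect_equal(rep$r["BVP", "EDA"], 0)
  expect_equal(rep$p["BVP", "EDA"], 1)
})

test_that("the C2ST separates disjoint supports and not permuted pools", {
  lo <- toy_window_set(40, seed = 2); lo$windows[] <- 0.1
  hi <- toy_window_set(40, seed = 3); hi$windows[] <- 0.9
  expect_gte(c2st(lo, hi, seed = 1)$accuracy[["both"]], 0.99)
  # permutation null: shuffling window identities within one pool
  pool <- small_windows(4)
  set.seed(10)
  idx <- sample(length(pool$labels))
  half <- length(idx) %/% 2
  a <- wearsynth:::ws_subset(pool, idx[1:half])
  b <- wearsynth:::ws_subset(pool, idx[(half + 1):(2 * half)])
  accs <- vapply(1:5, function(s) c2st(a, b, seed = s)$accuracy[["both"]], 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  expect_error(c2st(wearsynth:::ws_subset(pool, 1:2), b), "at least 4")
})

test_that("the internal Gaussian NB agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(6)
  X <- rbind(matrix(rnorm(200, 0), 50), matrix(rnorm(200, 1), 50))
  y <- rep(0:1, each = 50)
  Xte <- rbind(matrix(rnorm(80, 0), 20), matrix(rnorm(80, 1), 20))
  fit <- wearsynth:::gnb_fit(X, y)
  mine <- wearsynth:::gnb_predict(fit, Xte)
  ref <- as.integer(as.character(predict(
    e1071::naiveBayes(data.frame(X), factor(y)), data.frame(Xte))))
  expect_gte(mean(mine == ref), 0.95)
})

test_that("PCA embeddings project synthetic data into the real-data space", {
  ws <- toy_window_set(12, seed = 5)
  emb <- embed_2d(ws, ws, method = "pca")
  n <- length(ws$labels)
  expect_equal(emb$coords[1:n, c("dim1", "dim2")],
               emb$coords[n + 1:n, c("dim1", "dim2")],
               ignore_attr = TRUE)
  expect_equal(dim(emb$loadings), c(6L, 2L))
  # rank-1 data: first PC explains ~everything, loading on the varying channel
  ws1 <- toy_window_set(12, seed = 6)
  ws1$windows[] <- 0.5
  ws1$windows[, , 5] <- matrix(runif(12), 12, 60)  # EDA varies per window
  emb1 <- embed_2d(ws1, ws1, method = "pca")
  expect_gt(emb1$var_explained[1], 0.999)
  expect_gt(abs(emb1$loadings["EDA", 1]), 10 * max(abs(emb1$loadings[-5, 1])))
  expect_error(embed_2d(ws, ws, method = "umap"))
})

test_that("t-SNE embeds jointly, deterministically, and separates far clusters", {
  a <- toy_window_set(10, seed = 7); a$windows[] <- a$windows * 0.05
  b <- toy_window_set(10, seed = 8); b$windows[] <- 0.9 + b$windows * 0.05
  e1 <- embed_2d(a, b, method = "tsne", seed = 4)
  e2 <- embed_2d(a, b, method = "tsne", seed = 4)
  expect_equal(e1$coords, e2$coords)
  lab <- e1$coords$set
  d_within <- stats::dist(e1$coords[lab == "real", 1:2])
  centroid_gap <- sqrt(sum((colMeans(e1$coords[lab == "real", 1:2]) -
                              colMeans(e1$coords[lab != "real", 1:2]))^2))
  expect_gt(centroid_gap, stats::median(d_within))
})

test_that("density comparisons are normalized per stratum", {
  ws <- small_windows(4)
  d <- density_compare(ws, ws, "EDA")
  bw <- 1 / 50
  for (st in c("stress", "nonstress")) {
    expect_equal(sum(d[[st]]$real) * bw, 1, tolerance = 1e-10)
    expect_equal(d[[st]]$real, d[[st]]$synth)
  }
  # fixture stress EDA mass sits right of non-stress mass
  mean_of <- function(df) sum(df$mid * df$real) / sum(df$real)
  expect_gt(mean_of(d$stress), mean_of(d$nonstress))
  # uniform values give flat unit density
  u <- toy_window_set(20, seed = 9)
  du <- density_compare(u, u, "BVP")
  expect_equal(mean(du$stress$real), 1, tolerance = 0.1)
  expect_error(density_compare(ws, ws, "HR"), "signal")
  # an empty stratum is omitted and flagged
  ns <- wearsynth:::ws_subset(ws, which(ws$labels == 0L))
  dn <- density_compare(ns, ns, "EDA")
  expect_true("stress" %in% dn$omitted)
  expect_null(dn$stress)
})

test_that("average percentage change is symmetric and anchored at zero", {
  expect_equal(avg_pct_change(5, 5), 0)
  expect_equal(avg_pct_change(3, 1), 100)
  expect_error(avg_pct_change(2, -2), "nonzero")
  set.seed(11)
  for (i in 1:20) {
    ab <- runif(2, 0.1, 10)
    expect_equal(avg_pct_change(ab[1], ab[2]), avg_pct_change(ab[2], ab[1]))
  }
})
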
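test_that("per-example clipping bounds every gradient's global norm", {
  g_small <- list(a = matrix(0.3, 1, 2), b = matrix(0.2, 1, 1))  # norm ~0.47
  g_big <- list(a = matrix(4, 1, 1), b = matrix(0, 1, 1))        # norm 4
  out <- clip_per_example(list(g_small, g_big), C = 1)
  expect_identical(out[[1]], g_small)                  # under the bound: untouched
  expect_equal(out[[2]]$a[1, 1], 1)                    # scaled by 0.25
  expect_equal(wearsynth:::grad_global_norm(out[[2]]), 1, tolerance = 1e-12)
  # brute-force audit over random gradient sets
  set.seed(8)
  grads <- replicate(30, list(w = matrix(rnorm(6, 0, 2), 2),
                              b = matrix(rnorm(2, 0, 2), 1)),
                     simplify = FALSE)
  clipped <- clip_per_example(grads, C = 0.7)
  norms <- vapply(clipped, wearsynth:::grad_global_norm, 0)
  expect_true(all(norms <= 0.7 + 1e-9))
  raw <- vapply(grads, wearsynth:::grad_global_norm, 0)
  expect_identical(clipped[raw <= 0.7], grads[raw <= 0.7])
})

test_that("sliding-window accounting uses unique windows with doubled epochs", {
  expect_equal(sliding_window_accounting(1000, 496),
               list(unique_n = 496, epoch_multiplier = 2L))
  expect_equal(sliding_window_accounting(496, 496)$epoch_multiplier, 1L)
  expect_error(sliding_window_accounting(400, 496), "cannot be below")
  # fixture cohort: sliding count = 2*unique - subjects (71 vs 36 per subject)
  n30 <- length(small_windows(4, stride = 30)$labels)
  n60 <- length(small_windows(4, stride = 60)$labels)
  expect_equal(n30, 2L * n60 - 4L)
  expect_equal(sliding_window_accounting(n30, n60)$epoch_multiplier, 2L)
})

test_that("delta selection returns the largest power of ten below 1/n", {
  expect_equal(select_delta(496), 1e-3)
  expect_equal(select_delta(5), 1e-1)
  # scan exact powers of ten: strictly below 1/n
  for (k in 1:6) expect_equal(select_delta(10^k), 10^-(k + 1))
  # brute force over exponents for assorted n
  for (n in c(2, 17, 100, 3000)) {
    d <- select_delta(n)
    cand <- 10^seq(-12, 0)
    expect_equal(d, max(cand[cand < 1 / n]))
  }
})

test_that("the accountant is monotone and matches the Gaussian mechanism at q=1", {
  expect_lt(epsilon_spent(2, 0.01, 1000, 1e-3),
            epsilon_spent(1, 0.01, 1000, 1e-3))
  eps_steps <- vapply(c(10, 100, 1000, 5000), function(s)
    epsilon_spent(1, 0.05, s, 1e-3), 0)
  expect_true(all(diff(eps_steps) > 0))
  expect_identical(epsilon_spent(0, 0.1, 10, 1e-3), Inf)
  # closed-form analytic Gaussian mechanism as the single-step, q=1 oracle
  analytic_eps <- function(sigma, delta) {
    f <- function(e) stats::pnorm(1 / (2 * sigma) - e * sigma) -
      exp(e) * stats::pnorm(-1 / (2 * sigma) - e * sigma) - delta
    stats::uniroot(f, c(1e-6, 100))$root
  }
  for (sigma in c(1, 3)) {
    a <- analytic_eps(sigma, 1e-5)
    r <- epsilon_spent(sigma, 1, 1, 1e-5)
    expect_gte(r, a)              # the accountant is an upper bound
    expect_lt(r / a, 1.10)        # within 10% of the closed form
  }
})

test_that("noise calibration round-trips through the accountant for all budgets", {
  for (eps in c(10, 1, 0.1)) {
    spec <- privacy_spec(epsilon = eps, unique_n = 496L,
                         effective_epochs = 840L, delta = 1e-3,
                         batch_size = 8L)
    q <- 8 / 496
    steps <- ceiling(840 * 496 / 8)
    spent <- epsilon_spent(spec$sigma, q, steps, 1e-3)
    expect_lte(spent, eps)
    expect_gte(spent, eps * 0.99)  # smallest such sigma: lands just below
  }
  # stricter budget needs strictly more noise
  s10 <- privacy_spec(epsilon = 10)$sigma
  s1 <- privacy_spec(epsilon = 1)$sigma
  expect_gt(s1, s10)
  # non-private passthrough
  expect_equal(privacy_spec(epsilon = Inf)$sigma, 0)
})

test_that("only the discriminator's update path carries DP noise", {
  ws <- wearsynth:::ws_subset(small_windows(2), 1:24)
  spec <- privacy_spec(epsilon = 10, unique_n = 24L, effective_epochs = 2L,
                       delta = 1e-2, batch_size = 8L, epochs = 2L)
  cfg <- tiny_gan_config(privacy = spec)
  m <- cgan(ws, cfg)
  expect_true(m$noise_log$discriminator)
  expect_false(m$noise_log$generator)
  expect_equal(nrow(m$losses), 2L)
  # the generator's trajectory must be reproducible from the seed alone
  m2 <- cgan(ws, cfg)
  expect_identical(m$G, m2$G)
})
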
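test_that("invalid specs are rejected with the offending field named", {
  expect_error(fixture_spec(duration_s = 60), "duration_s")
  expect_error(fixture_spec(stress_fraction = 1.2), "stress_fraction")
  expect_error(fixture_spec(eda_shift = -1), "eda_shift")
  expect_error(fixture_spec(temp_shift = 0.5), "temp_shift")
  expect_error(fixture_spec(bvp_freq = c(nonstress = 2, stress = 1)),
               "bvp_freq")
  expect_error(fixture_spec(native_rates = c(ACC_x = 0.5, ACC_y = 32,
                                             ACC_z = 32, BVP = 64, EDA = 4,
                                             TEMP = 4)),
               "native_rates")
  expect_error(generate_cohort(fixture_spec(), 0), "n_subjects")
})

test_that("sessions realize the configured stress budget and structure", {
  spec <- fixture_spec(seed = 7)
  ses <- generate_session(spec, "S01")
  expect_length(ses$labels, 2160L)
  expect_true(all(ses$labels %in% 0:2))
  frac <- mean(ses$labels == 1L)
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
  # signal lengths match rate x duration
  for (s in e4_signals)
    expect_length(ses$signals[[s]]$values,
                  spec$native_rates[[s]] * 2160L)
  # stress seconds form 2-4 contiguous blocks
  r <- rle(ses$labels == 1L)
  expect_true(sum(r$values) %in% 2:4)
  # amusement seconds exist (exercises the 3-state relabeling downstream)
  expect_gt(sum(ses$labels == 2L), 0)
})

test_that("label budget holds across seeds", {
  for (seed in c(1, 33, 77)) {
    ses <- generate_session(fixture_spec(seed = seed), "SX")
    expect_lte(abs(mean(ses$labels == 1L) - 0.30), 0.05)
  }
})

test_that("stress raises EDA and lowers TEMP; checked by direct averaging", {
  spec <- fixture_spec(seed = 7)
  ses <- generate_session(spec, "S01")
  # independent pass: expand per-second labels to each native rate
  seg_means <- function(sig) {
    v <- ses$signals[[sig]]
    lab <- ses$labels[floor((seq_along(v$values) - 1) / v$rate) + 1]
    c(stress = mean(v$values[lab == 1]), other = mean(v$values[lab != 1]))
  }
  eda <- seg_means("EDA")
  expect_gt(eda[["stress"]] - eda[["other"]], 0)
  tmp <- seg_means("TEMP")
  expect_lt(tmp[["stress"]] - tmp[["other"]], 0)
  # dominant BVP frequency is higher in stress blocks (spectral argmax)
  dom_freq <- function(lab_target) {
    v <- ses$signals$BVP
    lab <- ses$labels[floor((seq_along(v$values) - 1) / v$rate) + 1]
    runs <- rle(lab == lab_target)
    ends <- cumsum(runs$lengths)
    i <- which(runs$values & runs$lengths > 60 * v$rate)[1]
    x <- v$values[(ends[i] - runs$lengths[i] + 1):ends[i]]
    sp <- Mod(stats::fft(x))[2:(length(x) %/% 2)]
    (which.max(sp)) / (length(x) / v$rate)
  }
  expect_gt(dom_freq(1L), dom_freq(0L))
})

test_that("no-effect, zero-noise spec yields equal EDA means", {
  spec <- fixture_spec(eda_shift = 0,
                       noise_sd = c(ACC_x = 0, ACC_y = 0, ACC_z = 0, BVP = 0,
                                    EDA = 0, TEMP = 0),
                       seed = 5)
  ses <- generate_session(spec, "S01")
  v <- ses$signals$EDA
  lab <- ses$labels[floor((seq_along(v$values) - 1) / v$rate) + 1]
  expect_equal(mean(v$values[lab == 1]), mean(v$values[lab != 1]))
})

test_that("cohorts are deterministic, with distinct subject ids", {
  spec <- fixture_spec(seed = 9, duration_s = 300)
  c1 <- generate_cohort(spec, 15)
  expect_length(c1, 15L)
  ids <- vapply(c1, `[[`, "", "subject_id")
  expect_false(anyDuplicated(ids) > 0)
  c2 <- generate_cohort(spec, 15)
  expect_identical(c1, c2)
  expect_length(generate_cohort(spec, 1), 1L)
})

test_that("cohort CSV round-trip preserves streams and labels", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 2, duration_s = 150)
  co <- generate_cohort(spec, 2)
  write_cohort(co, dir, spec)
  back <- read_cohort(dir)
  expect_identical(vapply(back, `[[`, "", "subject_id"),
                   vapply(co, `[[`, "", "subject_id"))
  expect_equal(back[[1]]$labels, co[[1]]$labels)
  expect_equal(back[[2]]$signals$EDA$values, co[[2]]$signals$EDA$values,
               tolerance = 1e-12)
})
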
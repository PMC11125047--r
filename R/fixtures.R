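# Synthetic Empatica-E4-like cohort generator.
#
# Emulates the statistical structure of a wrist-worn stress study: per-subject
# multi-rate channel streams (ACC x/y/z, BVP, EDA, TEMP) plus a per-second
# 3-state label track (0 neutral, 1 stress, 2 amusement). Stress physiology is
# encoded as directional effects: EDA elevated and TEMP depressed under
# stress, BVP oscillating at a higher frequency under stress, ACC carrying
# label-independent movement noise.

#' Specification for a synthetic wearable-stress cohort
#'
#' Defines the study conditions a generated cohort emulates: session length,
#' stress share, native sampling rates of the wrist channels, the directional
#' stress effect sizes, and noise levels.
#'
#' @param duration_s Session length in seconds (default 2160, i.e. 36 min).
#' @param stress_fraction Target share of stress-labeled seconds, in (0,1).
#' @param native_rates Named vector of sampling rates in Hz for the six
#'   channels (defaults: ACC 32 Hz, BVP 64 Hz, EDA 4 Hz, TEMP 4 Hz).
#' @param eda_shift Stress-minus-non-stress EDA mean shift in microsiemens
#'   (must be positive).
#' @param temp_shift Stress-minus-non-stress skin-temperature shift in degrees
#'   Celsius (must be negative).
#' @param bvp_freq Length-2 named vector `c(nonstress=, stress=)` of dominant
#'   BVP oscillation frequencies in Hz; the stress frequency must be larger.
#' @param noise_sd Named vector of per-channel noise standard deviations.
#' @param amusement_share Share of non-stress seconds carrying the amusement
#'   label code 2.
#' @param seed Integer seed; all generation is deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(duration_s = 2160,
                         stress_fraction = 0.30,
                         native_rates = c(ACC_x = 32, ACC_y = 32, ACC_z = 32,
                                          BVP = 64, EDA = 4, TEMP = 4),
                         eda_shift = 4,
                         temp_shift = -1,
                         bvp_freq = c(nonstress = 1.1, stress = 1.6),
                         noise_sd = c(ACC_x = 0.5, ACC_y = 0.5, ACC_z = 0.5,
                                      BVP = 8, EDA = 0.25, TEMP = 0.05),
                         amusement_share = 0.10,
                         seed = 1L) {
  spec <- structure(
    list(duration_s = duration_s, stress_fraction = stress_fraction,
         native_rates = native_rates, eda_shift = eda_shift,
         temp_shift = temp_shift, bvp_freq = bvp_freq, noise_sd = noise_sd,
         amusement_share = amusement_share, seed = as.integer(seed)),
    class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  if (!is.numeric(spec$duration_s) || spec$duration_s < 120)
    stop_field("duration_s", "must be at least 120 seconds")
  if (spec$stress_fraction <= 0 || spec$stress_fraction >= 1)
    stop_field("stress_fraction", "must lie strictly between 0 and 1")
  if (!all(e4_signals %in% names(spec$native_rates)))
    stop_field("native_rates", "must name all six channels")
  if (any(spec$native_rates < 1))
    stop_field("native_rates", "all rates must be at least 1 Hz")
  if (spec$eda_shift < 0)
    stop_field("eda_shift", "must be non-negative (EDA rises under stress)")
  if (spec$temp_shift > 0)
    stop_field("temp_shift", "must be non-positive (TEMP falls under stress)")
  if (spec$bvp_freq[["stress"]] <= spec$bvp_freq[["nonstress"]])
    stop_field("bvp_freq", "stress frequency must exceed non-stress frequency")
  if (spec$amusement_share < 0 || spec$amusement_share >= 1)
    stop_field("amusement_share", "must lie in [0,1)")
  invisible(spec)
}

# Stationary AR(1) noise with marginal sd `sd` and lag-1 coefficient `phi`.
ar1_noise <- function(n, sd, phi = 0.95) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive", init = stats::rnorm(1, 0, sd)))
}

# Draw a 3-state label track: 2-4 contiguous stress blocks summing to the
# stress budget, plus one contiguous amusement block within the longest
# non-stress gap.
draw_label_track <- function(spec) {
  T <- as.integer(spec$duration_s)
  stress_total <- round(spec$stress_fraction * T)
  n_blocks <- sample(2:4, 1L)
  # block lengths: random positive proportions of the stress budget
  p <- stats::rgamma(n_blocks, shape = 3)
  lens <- pmax(1L, round(stress_total * p / sum(p)))
  lens[n_blocks] <- max(1L, stress_total - sum(lens[-n_blocks]))
  # gap lengths around the blocks (n_blocks + 1 gaps)
  gap_total <- T - sum(lens)
  g <- stats::rgamma(n_blocks + 1L, shape = 3)
  gaps <- pmax(1L, round(gap_total * g / sum(g)))
  excess <- sum(gaps) - gap_total
  gaps[which.max(gaps)] <- max(1L, gaps[which.max(gaps)] - excess)
  lab <- integer(0)
  for (i in seq_len(n_blocks)) lab <- c(lab, integer(gaps[i]), rep(1L, lens[i]))
  lab <- c(lab, integer(gaps[n_blocks + 1L]))
  if (length(lab) < T) lab <- c(lab, integer(T - length(lab)))
  lab <- lab[seq_len(T)]
  # amusement: contiguous run inside the longest non-stress gap
  amu_len <- round(spec$amusement_share * sum(lab == 0L))
  if (amu_len > 0) {
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    zi <- which(r$values == 0L)
    gi <- zi[which.max(r$lengths[zi])]
    len <- min(amu_len, r$lengths[gi])
    at <- starts[gi] + (r$lengths[gi] - len) %/% 2L
    lab[at:(at + len - 1L)] <- 2L
  }
  lab
}

#' Generate one synthetic subject session
#'
#' Produces multi-rate channel streams and a per-second 3-state label track
#' with the configured stress physiology: contiguous stress blocks, elevated
#' EDA and depressed TEMP during stress, faster BVP oscillation under stress,
#' and AR(1)-smoothed channel noise. Deterministic given `spec$seed` and
#' `subject_id`.
#'
#' @param spec A [fixture_spec()].
#' @param subject_id Character subject identifier.
#' @return A `raw_session`: list with `subject_id`, `signals` (per channel a
#'   list of `rate` and `values`), and `labels` (one code per second;
#'   0 neutral, 1 stress, 2 amusement).
#' @export
generate_session <- function(spec, subject_id) {
  validate_fixture_spec(spec)
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  with_seed(derive_seed(spec$seed, "session", subject_id), {
    T <- as.integer(spec$duration_s)
    labels <- draw_label_track(spec)
    stress <- as.integer(labels == 1L)
    sig <- list()
    # per-subject baselines (inter-subject variability)
    eda_base <- 2.0 + stats::rnorm(1, 0, 0.5)
    temp_base <- 33.5 + stats::rnorm(1, 0, 0.4)
    acc_off <- c(-0.5, 0.2, 0.8) + stats::rnorm(3, 0, 0.1)
    for (s in e4_signals) {
      fs <- spec$native_rates[[s]]
      n <- as.integer(fs * T)
      stress_smp <- stress[pmin(T, floor((seq_len(n) - 1) / fs) + 1L)]
      base <- switch(s,
        EDA  = eda_base + spec$eda_shift * stress_smp,
        TEMP = temp_base + spec$temp_shift * stress_smp,
        BVP  = {
          f <- ifelse(stress_smp == 1L, spec$bvp_freq[["stress"]],
                      spec$bvp_freq[["nonstress"]])
          40 * sin(cumsum(2 * pi * f / fs))
        },
        acc_off[match(s, c("ACC_x", "ACC_y", "ACC_z"))])
      if (length(base) == 1L) base <- rep(base, n)
      sig[[s]] <- list(rate = fs, values = base + ar1_noise(n, spec$noise_sd[[s]]))
    }
    structure(list(subject_id = subject_id, signals = sig, labels = labels),
              class = "raw_session")
  })
}

#' Generate a cohort of synthetic subjects
#'
#' @param spec A [fixture_spec()].
#' @param n_subjects Number of subjects (>= 1); identifiers are `S01`, `S02`, ...
#' @return List of `raw_session` objects with distinct subject ids.
#' @export
generate_cohort <- function(spec, n_subjects) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_field("n_subjects", "must be at least 1")
  ids <- sprintf("S%02d", seq_len(n_subjects))
  lapply(ids, function(id) generate_session(spec, id))
}

#' Write a cohort to a directory of plain-text files
#'
#' One sub-directory per subject with a `time_s,value` CSV per channel and a
#' `labels.csv` (`second,label`), plus a JSON manifest of the spec.
#' @param cohort List of `raw_session` objects.
#' @param dir Output directory (created if absent).
#' @param spec The [fixture_spec()] used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ses in cohort) {
    sd <- file.path(dir, ses$subject_id)
    dir.create(sd, showWarnings = FALSE)
    for (s in names(ses$signals)) {
      v <- ses$signals[[s]]
      utils::write.csv(
        data.frame(time_s = (seq_along(v$values) - 1) / v$rate, value = v$values),
        file.path(sd, paste0(s, ".csv")), row.names = FALSE)
    }
    utils::write.csv(
      data.frame(second = seq_along(ses$labels) - 1L, label = ses$labels),
      file.path(sd, "labels.csv"), row.names = FALSE)
  }
  manifest <- list(subjects = vapply(cohort, `[[`, "", "subject_id"),
                   rates = as.list(cohort[[1]]$signals |>
                                     vapply(`[[`, 0, "rate")))
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory.
#' @return List of `raw_session` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$subjects, function(id) {
    sd <- file.path(dir, id)
    sig <- lapply(e4_signals, function(s) {
      d <- utils::read.csv(file.path(sd, paste0(s, ".csv")))
      rate <- manifest$rates[[s]]
      list(rate = rate, values = d$value)
    })
    names(sig) <- e4_signals
    lab <- utils::read.csv(file.path(sd, "labels.csv"))$label
    structure(list(subject_id = id, signals = sig, labels = as.integer(lab)),
              class = "raw_session")
  })
}
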
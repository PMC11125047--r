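# Leave-one-subject-out evaluation harness: fold construction, training-set
# composition (ORIG / TSTR / AUGM), the full repeated LOSO experiment, and
# the logistic-regression baseline sweep over signal combinations.

#' Leave-one-subject-out folds
#'
#' One fold per subject: the subject is the test set, all others train. Any
#' generator trained inside a fold must also exclude the test subject.
#'
#' @param subject_ids Character vector of distinct ids (>= 2).
#' @return List of folds, each `list(test = id, train = other ids)`.
#' @export
loso_folds <- function(subject_ids) {
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids", call. = FALSE)
  if (length(subject_ids) < 2) stop("need at least 2 subjects", call. = FALSE)
  lapply(subject_ids, function(id)
    list(test = id, train = setdiff(subject_ids, id)))
}

#' Compose a training window set for a strategy
#'
#' `ORIG` uses the fold's real windows, `TSTR` only the synthetic cohort,
#' `AUGM` the concatenation of both. Subject ids (provenance) are retained
#' per window.
#'
#' @param fold_windows [window_set()] of the fold's real training subjects.
#' @param strategy `"ORIG"`, `"TSTR"` or `"AUGM"`.
#' @param synth Synthetic [window_set()] (required unless `ORIG`).
#' @return A [window_set()].
#' @export
compose_training <- function(fold_windows, strategy = c("ORIG", "TSTR", "AUGM"),
                             synth = NULL) {
  strategy <- match.arg(strategy)
  if (strategy != "ORIG" && is.null(synth))
    stop(sprintf("%s requires a synthetic cohort", strategy), call. = FALSE)
  switch(strategy,
         ORIG = fold_windows,
         TSTR = synth,
         AUGM = c(fold_windows, synth))
}

#' Plan for a repeated LOSO experiment
#'
#' @param strategy `"ORIG"`, `"TSTR"` or `"AUGM"`.
#' @param synth_subjects Synthetic subjects generated per fold (e.g. 15 or
#'   100).
#' @param epsilon Privacy budget for the fold GANs / classifier (`Inf` for
#'   non-private).
#' @param classifier A [classifier_config()].
#' @param gan A [gan_config()] for the per-fold generators.
#' @param repeats Full LOSO repetitions averaged into the final score.
#' @param gan_stride_s Stride for the generator's training windows (30 adds
#'   sliding windows; classifiers always train on 60-s strides of real data).
#' @param shared_gan Train one generator on all subjects instead of one per
#'   fold. Cheaper, but not LOSO-conform; flagged in the report.
#' @param seed Base seed.
#' @return Object of class `experiment_plan`.
#' @export
experiment_plan <- function(strategy = c("ORIG", "TSTR", "AUGM"),
                            synth_subjects = 15L, epsilon = Inf,
                            classifier = classifier_config("cnn"),
                            gan = gan_config(), repeats = 10L,
                            gan_stride_s = 30L, shared_gan = FALSE,
                            seed = 42L) {
  strategy <- match.arg(strategy)
  if (repeats < 1) stop_field("repeats", "must be at least 1")
  structure(list(strategy = strategy,
                 synth_subjects = as.integer(synth_subjects),
                 epsilon = epsilon, classifier = classifier, gan = gan,
                 repeats = as.integer(repeats),
                 gan_stride_s = as.integer(gan_stride_s),
                 shared_gan = isTRUE(shared_gan), seed = as.integer(seed)),
            class = "experiment_plan")
}

#' Run a repeated LOSO stress-classification experiment
#'
#' For every repeat and fold: (for TSTR/AUGM) train a fold generator on the
#' training subjects only, synthesize a cohort, compose the training set per
#' the strategy, featurize, train the classifier (privately when the plan's
#' epsilon is finite), and evaluate on the held-out real subject. Per-fold
#' metrics and their unweighted mean (over folds, then repeats) are reported.
#'
#' @param plan An [experiment_plan()].
#' @param cohort List of `raw_session` objects (the real cohort).
#' @return Object of class `run_report`: `folds` (data.frame of per-repeat,
#'   per-fold metrics) and `aggregate` (mean and sd of F1, precision,
#'   recall, accuracy).
#' @export
run_experiment <- function(plan, cohort) {
  ids <- vapply(cohort, `[[`, "", "subject_id")
  folds <- loso_folds(ids)
  rows <- list()
  for (rep_i in seq_len(plan$repeats)) {
    rep_seed <- plan$seed + rep_i - 1L
    shared_model <- NULL
    if (plan$strategy != "ORIG" && plan$shared_gan) {
      prep_all <- prepare_cohort(cohort, stride_s = plan$gan_stride_s)
      gcfg <- plan$gan
      gcfg$seed <- derive_seed(rep_seed, "shared-gan")
      shared_model <- cgan(prep_all$windows, gcfg)
    }
    for (fold in folds) {
      fold_seed <- derive_seed(rep_seed, fold$test)
      train_ses <- cohort[ids %in% fold$train]
      test_ses <- cohort[ids == fold$test]
      # classifiers train on clean 60-s windows of the real data
      prep_train <- prepare_cohort(train_ses, stride_s = 60L)
      prep_test <- prepare_cohort(test_ses, stride_s = 60L,
                                  stats = prep_train$stats)
      synth <- NULL
      if (plan$strategy != "ORIG") {
        model <- if (plan$shared_gan) shared_model else {
          gcfg <- plan$gan
          gcfg$seed <- fold_seed
          if (is.finite(plan$epsilon)) {
            gan_prep <- prepare_cohort(train_ses, stride_s = plan$gan_stride_s)
            acct <- sliding_window_accounting(
              length(gan_prep$windows$labels), length(prep_train$windows$labels))
            gcfg$privacy <- privacy_spec(
              epsilon = plan$epsilon, unique_n = acct$unique_n,
              effective_epochs = acct$epoch_multiplier * gcfg$epochs,
              epochs = gcfg$epochs)
          } else {
            gan_prep <- prepare_cohort(train_ses, stride_s = plan$gan_stride_s)
          }
          cgan(gan_prep$windows, gcfg)
        }
        synth <- synthesize_subjects(model, plan$synth_subjects,
                                     seed = derive_seed(fold_seed, "synth"))
      }
      train_ws <- compose_training(prep_train$windows, plan$strategy, synth)
      tr_feats <- featurize_windows(train_ws)
      te_feats <- featurize_windows(prep_test$windows)
      ccfg <- plan$classifier
      ccfg$seed <- derive_seed(fold_seed, "clf")
      if (is.finite(plan$epsilon) && plan$strategy != "TSTR") {
        # real windows in training: the classifier itself must train with DP
        ccfg$privacy <- privacy_spec(
          epsilon = plan$epsilon,
          unique_n = length(prep_train$windows$labels),
          effective_epochs = ccfg$epochs, epochs = ccfg$epochs,
          batch_size = ccfg$batch_size)
      }
      clf <- stress_classifier(tr_feats, ccfg)
      m <- evaluate_classifier(clf, te_feats)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_i = rep_i, subject = fold$test, precision = m$precision,
        recall = m$recall, f1 = m$f1, accuracy = m$accuracy,
        tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn, seed = fold_seed)
    }
  }
  folds_df <- do.call(rbind, rows)
  agg <- c(f1 = mean(folds_df$f1), precision = mean(folds_df$precision),
           recall = mean(folds_df$recall), accuracy = mean(folds_df$accuracy))
  sdv <- c(f1 = stats::sd(folds_df$f1), precision = stats::sd(folds_df$precision),
           recall = stats::sd(folds_df$recall),
           accuracy = stats::sd(folds_df$accuracy))
  structure(list(folds = folds_df, aggregate = agg, aggregate_sd = sdv,
                 plan = plan, loso_conform = !plan$shared_gan),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s, %d folds x %d repeats%s\n",
              x$plan$strategy, length(unique(x$folds$subject)),
              x$plan$repeats,
              if (!x$loso_conform) " [shared GAN: not LOSO-conform]" else ""))
  cat(sprintf("  mean F1=%.4f P=%.4f R=%.4f acc=%.4f\n",
              x$aggregate[["f1"]], x$aggregate[["precision"]],
              x$aggregate[["recall"]], x$aggregate[["accuracy"]]))
  invisible(x)
}

#' Baseline logistic-regression sweep over signal combinations
#'
#' Fits a logistic regression on per-window mean spectral power, for every
#' non-empty subset of the six channels, in the LOSO setting; reports the
#' mean F1 per subset, the coefficients of the all-signal model, and each
#' channel's average percentage change of mean spectral power between stress
#' and non-stress windows.
#'
#' @param power Matrix `N x 6` of per-window mean spectral power (see the
#'   `power` option of [featurize_windows()]).
#' @param subject_ids Character vector of length `N`.
#' @param labels Binary vector of length `N`.
#' @return List: `table` (data.frame of 63 subsets with mean F1),
#'   `coefficients` (all-signal model, averaged over folds), `pct_change`
#'   (named per-channel vector), `skipped_folds`.
#' @export
baseline_signal_sweep <- function(power, subject_ids, labels) {
  stopifnot(nrow(power) == length(labels), length(subject_ids) == length(labels))
  colnames(power) <- e4_signals
  subjects <- unique(subject_ids)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  folds <- loso_folds(subjects)
  subsets <- lapply(seq_len(2^6 - 1), function(m) which(bitwAnd(m, 2^(0:5)) > 0))
  skipped <- character(0)
  fold_fit <- function(cols, fold) {
    tr <- subject_ids %in% fold$train
    te <- subject_ids == fold$test
    if (length(unique(labels[tr])) < 2) return(NULL)
    d_tr <- data.frame(y = labels[tr], power[tr, cols, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = d_tr, family = stats::binomial()))
    pr <- as.integer(stats::predict(
      fit, data.frame(power[te, cols, drop = FALSE]), type = "response") >= 0.5)
    y <- labels[te]
    m <- confusion_metrics(sum(pr == 1 & y == 1), sum(pr == 1 & y == 0),
                           sum(pr == 0 & y == 1), sum(pr == 0 & y == 0))
    list(f1 = m$f1, coef = stats::coef(fit))
  }
  tab <- data.frame(subset = vapply(subsets, function(s)
    paste(e4_signals[s], collapse = "+"), ""), mean_f1 = NA_real_)
  all_coefs <- NULL
  for (k in seq_along(subsets)) {
    f1s <- c(); coefs <- list()
    for (fold in folds) {
      r <- fold_fit(subsets[[k]], fold)
      if (is.null(r)) {
        skipped <- unique(c(skipped, fold$test)); next
      }
      f1s <- c(f1s, r$f1)
      if (length(subsets[[k]]) == 6L) coefs[[length(coefs) + 1L]] <- r$coef
    }
    tab$mean_f1[k] <- mean(f1s)
    if (length(coefs)) all_coefs <- Reduce(`+`, coefs) / length(coefs)
  }
  pct <- vapply(seq_len(6L), function(c)
    avg_pct_change(mean(power[labels == 1, c]), mean(power[labels == 0, c])),
    0)
  names(pct) <- e4_signals
  list(table = tab[order(-tab$mean_f1), ], coefficients = all_coefs,
       pct_change = pct, skipped_folds = skipped)
}
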
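#' Information transfer rate (bits/min)
#'
#' Wolpaw-style ITR of a K-class selector:
#' `60 * (log2(K) + P*log2(P) + (1-P)*log2((1-P)/(K-1))) / T`, with the
#' convention `0*log2(0) = 0`. Accuracies below chance (`P < 1/K`) are
#' clipped to chance — where the formula would otherwise go negative — giving
#' an ITR floor of 0; a message reports the clip.
#'
#' @param K number of targets (>= 2).
#' @param P classification accuracy in `[0, 1]`; vectorized.
#' @param T_s target selection time in seconds, conventionally the analysis
#'   window plus a 0.55 s gaze shift.
#' @return ITR in bits/min, same length as `P`.
#' @export
itr <- function(K, P, T_s) {
  stopifnot(K >= 2, T_s > 0, all(P >= 0), all(P <= 1))
  clipped <- P < 1 / K
  if (any(clipped))
    message(sum(clipped), " accuracy value(s) below chance 1/K clipped to chance (ITR 0)")
  P <- pmax(P, 1 / K)
  plog <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(K) + plog(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (K - 1)), 0)
  pmax(60 * bits / T_s, 0)
}

#' Paired comparison of per-fold metrics
#'
#' Two-sided paired t-test between matched per-fold (or per-subject) metric
#' vectors, with the significance bands used in BCI reporting:
#' `ns` (p >= 0.05), `*` (p < 0.05), `**` (p < 0.01), `***` (p < 0.001).
#' If the paired differences have zero variance the t statistic is
#' degenerate; the comparison then returns p = 1 (`ns`) for identical
#' vectors and p = 0 (`***`) for a constant nonzero shift.
#'
#' @param a,b numeric vectors of equal length, or `eval_report` objects
#'   (their per-fold accuracies are compared).
#' @return A list with `t`, `df`, `p_value`, `band`, `mean_diff` (a - b).
#' @export
paired_compare <- function(a, b) {
  if (inherits(a, "eval_report")) a <- a$folds$accuracy
  if (inherits(b, "eval_report")) b <- b$folds$accuracy
  if (length(a) != length(b))
    stop("paired vectors differ in length: ", length(a), " vs ", length(b))
  if (length(a) < 2) stop("need at least two pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(d)) * Inf; p <- 0
    }
    df <- length(d) - 1
  } else {
    ht <- stats::t.test(a, b, paired = TRUE)
    t <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  band <- if (p >= 0.05) "ns" else if (p >= 0.01) "*"
          else if (p >= 0.001) "**" else "***"
  list(t = t, df = df, p_value = p, band = band, mean_diff = mean(d))
}

new_eval_report <- function(protocol, folds, window_s, n_classes,
                            gaze_shift_s) {
  T_s <- window_s + gaze_shift_s
  structure(
    list(protocol = protocol, folds = folds, window_s = window_s,
         n_classes = n_classes, gaze_shift_s = gaze_shift_s,
         selection_time_s = T_s,
         mean_accuracy = mean(folds$accuracy),
         sem_accuracy = stats::sd(folds$accuracy) / sqrt(nrow(folds)),
         mean_itr = mean(folds$itr),
         itr_of_mean_accuracy = itr(n_classes, mean(folds$accuracy), T_s),
         note = "raw per-fold paired tests; no multiple-testing correction"),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s evaluation: %d folds, %d classes, %.2g s window (+%.2f s gaze shift)\n",
              x$protocol, nrow(x$folds), x$n_classes, x$window_s,
              x$gaze_shift_s))
  cat(sprintf("  accuracy %.1f%% +/- %.1f%% (SEM)\n",
              100 * x$mean_accuracy, 100 * x$sem_accuracy))
  cat(sprintf("  ITR: mean of per-fold ITRs %.2f bits/min; ITR of mean accuracy %.2f bits/min\n",
              x$mean_itr, x$itr_of_mean_accuracy))
  invisible(x)
}

prepare_features <- function(epochs, window_s, band, filter_order,
                             resolution, feat_band, apply_filter) {
  if (apply_filter) epochs <- bandpass_filter(epochs, band, filter_order)
  segs <- segment_epochs(epochs, window_s)
  spectrum_features(segs, resolution = resolution, band = feat_band)
}

fit_fold <- function(builder, cfg, train_feats, fold_cfg) {
  set.seed(fold_cfg$seed)
  model <- builder(cfg)
  train_decoder(model, train_feats, fold_cfg)
}

fold_seed <- function(seed, fold) as.integer((seed + 7919 * fold) %% 2147483647)

#' Leave-one-subject-out (subject-independent) cross-validation
#'
#' Trials are filtered, segmented and transformed to complex-spectrum
#' features once; then each fold trains on all segments of n-1 subjects and
#' tests on the held-out subject, so no subject ever contributes to both
#' sides. Weight initialization, shuffling and dropout are re-seeded per
#' fold from `train_cfg$seed`, making the report reproducible.
#'
#' @param epochs multi-subject [eeg_epochs] (>= 2 subjects).
#' @param model_builder [build_atten_ccnn] or [build_ccnn].
#' @param window_s analysis window in seconds.
#' @param train_cfg a [train_config()]; default batch size 256 as used for
#'   the subject-independent protocol.
#' @param band,filter_order zero-phase Butterworth band-pass settings
#'   (skipped when `apply_filter = FALSE`).
#' @param resolution,feat_band complex-spectrum settings, see
#'   [complex_spectrum()].
#' @param gaze_shift_s inter-selection gaze shift added to the window when
#'   computing ITR; default 0.55 s.
#' @param apply_filter set `FALSE` if `epochs` are already filtered.
#' @param model_args named list forwarded to [model_config()] (e.g.
#'   `se_ratio`).
#' @param holdout_subjects optional subset of subject ids to hold out; by
#'   default every subject is held out once. Each listed subject still
#'   trains on all remaining subjects, so this evaluates a subset of the
#'   LOSO folds (useful when full rotation is too expensive).
#' @param verbose print per-fold progress.
#' @return An `eval_report` with one row per held-out subject.
#' @export
loso_cv <- function(epochs, model_builder = build_atten_ccnn, window_s = 1,
                    train_cfg = train_config(batch_size = 256L),
                    band = c(3, 45), filter_order = 4,
                    resolution = 0.25, feat_band = c(3, 35),
                    gaze_shift_s = 0.55, apply_filter = TRUE,
                    model_args = list(), holdout_subjects = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  all_subjects <- unique(epochs$subject_ids)
  if (length(all_subjects) < 2)
    stop("leave-one-subject-out needs >= 2 subjects; ",
         "use kfold_cv() for single-subject (subject-dependent) evaluation")
  subjects <- if (is.null(holdout_subjects)) all_subjects else {
    missing <- setdiff(holdout_subjects, all_subjects)
    if (length(missing) > 0)
      stop("unknown holdout subject(s): ", paste(missing, collapse = ", "))
    holdout_subjects
  }
  feats <- prepare_features(epochs, window_s, band, filter_order,
                            resolution, feat_band, apply_filter)
  cfg <- do.call(model_config, c(list(
    n_channels = dim(feats$features)[2],
    n_features = dim(feats$features)[3],
    n_classes = feats$n_classes), model_args))

  rows <- vector("list", length(subjects))
  preds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    test_idx <- which(feats$subject_ids == subjects[i])
    train_idx <- which(feats$subject_ids != subjects[i])
    stopifnot(length(intersect(feats$subject_ids[train_idx],
                               feats$subject_ids[test_idx])) == 0)
    fold_cfg <- train_cfg
    fold_cfg$seed <- fold_seed(train_cfg$seed, i)
    model <- fit_fold(model_builder, cfg, subset_features(feats, train_idx),
                      fold_cfg)
    pred <- predict(model, subset_features(feats, test_idx))
    acc <- mean(pred == feats$labels[test_idx])
    rows[[i]] <- data.frame(fold = i, subject = subjects[i],
                            n_test = length(test_idx), accuracy = acc,
                            itr = itr(feats$n_classes, acc,
                                      window_s + gaze_shift_s))
    preds[[i]] <- data.frame(fold = i, segment = test_idx,
                             subject = feats$subject_ids[test_idx],
                             label = feats$labels[test_idx],
                             predicted = pred)
    if (verbose)
      message(sprintf("fold %d (%s held out): accuracy %.3f", i,
                      subjects[i], acc))
  }
  rpt <- new_eval_report("subject-independent (LOSO)", do.call(rbind, rows),
                         window_s, feats$n_classes, gaze_shift_s)
  rpt$predictions <- do.call(rbind, preds)
  rpt
}

#' 10-fold (subject-dependent) cross-validation
#'
#' One subject's trials are segmented into non-overlapping windows and the
#' segments are partitioned into `k` random sets (seeded); each set is
#' tested once against a model trained on the remaining k-1 sets. Note that
#' the segment-level random partition can place segments of one trial on
#' both sides of a fold — that is the protocol as specified, and it makes
#' subject-dependent accuracies optimistic relative to a trial-level split.
#'
#' @param epochs single-subject [eeg_epochs].
#' @param k number of folds (default 10).
#' @param train_cfg a [train_config()]; default batch size 16 as used for
#'   the subject-dependent protocol.
#' @inheritParams loso_cv
#' @return An `eval_report` with one row per fold.
#' @export
kfold_cv <- function(epochs, model_builder = build_atten_ccnn, window_s = 1,
                     train_cfg = train_config(batch_size = 16L), k = 10L,
                     band = c(3, 45), filter_order = 4,
                     resolution = 0.25, feat_band = c(3, 35),
                     gaze_shift_s = 0.55, apply_filter = TRUE,
                     model_args = list(), verbose = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  subjects <- unique(epochs$subject_ids)
  if (length(subjects) > 1)
    stop("kfold_cv is subject-dependent: pass one subject's epochs ",
         "(got ", length(subjects), " subjects)")
  feats <- prepare_features(epochs, window_s, band, filter_order,
                            resolution, feat_band, apply_filter)
  n <- dim(feats$features)[1]
  if (n < k) stop("fewer segments (", n, ") than folds (", k, ")")
  cfg <- do.call(model_config, c(list(
    n_channels = dim(feats$features)[2],
    n_features = dim(feats$features)[3],
    n_classes = feats$n_classes), model_args))

  set.seed(train_cfg$seed)
  fold_of <- sample(rep(seq_len(k), length.out = n))

  rows <- vector("list", k)
  preds <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- which(fold_of == i)
    train_idx <- which(fold_of != i)
    fold_cfg <- train_cfg
    fold_cfg$seed <- fold_seed(train_cfg$seed, i)
    model <- fit_fold(model_builder, cfg, subset_features(feats, train_idx),
                      fold_cfg)
    pred <- predict(model, subset_features(feats, test_idx))
    acc <- mean(pred == feats$labels[test_idx])
    rows[[i]] <- data.frame(fold = i, subject = subjects[1],
                            n_test = length(test_idx), accuracy = acc,
                            itr = itr(feats$n_classes, acc,
                                      window_s + gaze_shift_s))
    preds[[i]] <- data.frame(fold = i, segment = test_idx,
                             subject = feats$subject_ids[test_idx],
                             label = feats$labels[test_idx],
                             predicted = pred)
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.3f", i, k, acc))
  }
  rpt <- new_eval_report(sprintf("subject-dependent (%d-fold)", k),
                         do.call(rbind, rows),
                         window_s, feats$n_classes, gaze_shift_s)
  rpt$predictions <- do.call(rbind, preds)
  rpt
}
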
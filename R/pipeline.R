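#' Full pipeline configuration
#'
#' A nested, fully-defaulted configuration describing one end-to-end run:
#' data source (synthetic generator settings or an epoch-container path),
#' preprocessing, model, training and evaluation protocol. Every field has
#' a default, so `run_config()` alone is a valid configuration; it
#' round-trips losslessly through JSON ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param preset stimulus layout preset, see [build_layout()].
#' @param epochs_path optional path to an epoch container written by
#'   [write_epochs()]; when set, the generator settings are ignored.
#' @param n_subjects,n_blocks,duration,fs,n_channels,snr_range synthetic
#'   generator settings, see [generate_dataset()].
#' @param channels optional channel-name subset applied after loading.
#' @param band,filter_order Butterworth band-pass settings.
#' @param resolution,feat_band,window_s complex-spectrum settings.
#' @param arch `"atten_ccnn"` or `"ccnn"`.
#' @param se_ratio,n_filters,conv2_kernel,dense_width,dropout,l2 model
#'   settings, see [model_config()].
#' @param protocol `"subject_independent"` (LOSO) or `"subject_dependent"`
#'   (10-fold per subject).
#' @param k folds for the subject-dependent protocol.
#' @param learning_rate,epochs,batch_size,momentum training settings; a
#'   `NULL` batch size picks the protocol default (256 LOSO / 16 k-fold).
#' @param gaze_shift_s gaze shift used in ITR.
#' @param seed master seed for the whole run.
#' @param out_dir optional artifact directory.
#' @return A list of class `ssvep_run_config`.
#' @export
run_config <- function(preset = "dataset2_12class", epochs_path = NULL,
                       n_subjects = 2L, n_blocks = 2L, duration = 2,
                       fs = 256, n_channels = 3L, snr_range = c(0, 10),
                       channels = NULL,
                       band = c(3, 45), filter_order = 4L,
                       resolution = 0.25, feat_band = c(3, 35),
                       window_s = 1,
                       arch = c("atten_ccnn", "ccnn"),
                       se_ratio = 4L, n_filters = 32L, conv2_kernel = 20L,
                       dense_width = 144L, dropout = 0.25, l2 = 0.001,
                       protocol = c("subject_dependent", "subject_independent"),
                       k = 10L,
                       learning_rate = 0.001, epochs = 120L,
                       batch_size = NULL, momentum = 0.9,
                       gaze_shift_s = 0.55, seed = 1L, out_dir = NULL) {
  arch <- match.arg(arch)
  protocol <- match.arg(protocol)
  structure(
    list(
      data = list(preset = preset, epochs_path = epochs_path,
                  n_subjects = as.integer(n_subjects),
                  n_blocks = as.integer(n_blocks), duration = duration,
                  fs = fs, n_channels = as.integer(n_channels),
                  snr_range = snr_range, channels = channels),
      preprocess = list(band = band, filter_order = as.integer(filter_order),
                        resolution = resolution, feat_band = feat_band,
                        window_s = window_s),
      model = list(arch = arch, se_ratio = as.integer(se_ratio),
                   n_filters = as.integer(n_filters),
                   conv2_kernel = as.integer(conv2_kernel),
                   dense_width = as.integer(dense_width),
                   dropout = dropout, l2 = l2),
      protocol = protocol, k = as.integer(k),
      train = list(learning_rate = learning_rate, epochs = as.integer(epochs),
                   batch_size = if (is.null(batch_size)) NULL
                                else as.integer(batch_size),
                   momentum = momentum),
      gaze_shift_s = gaze_shift_s,
      seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "ssvep_run_config"
  )
}

#' @rdname run_config
#' @param config an `ssvep_run_config`.
#' @param path file path (`.json`, or `.yaml`/`.yml` for reading when the
#'   yaml package is installed).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # rebuild through the constructor so defaults, classes and validation are
  # canonical regardless of which optional fields the file spells out
  args <- c(raw$data, raw$preprocess, raw$model, raw$train,
            raw[c("protocol", "k", "gaze_shift_s", "seed", "out_dir")])
  args <- args[!vapply(args, is.null, logical(1))]
  args <- args[names(args) %in% names(formals(run_config))]
  do.call(run_config, args)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full decoding pipeline
#'
#' Load or simulate epochs, band-pass filter, segment, extract
#' complex-spectrum features, run the configured cross-validation protocol
#' and (optionally) write artifacts: the effective configuration, a run log,
#' the per-fold table, per-segment predictions, and the evaluation report.
#' Everything is derived from `config$seed`, so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param config an [run_config()] object.
#' @return The `eval_report` (for the subject-dependent protocol, fold rows
#'   of all subjects are pooled and per-subject accuracies appear in
#'   `$per_subject`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ssvep_run_config"))
  log_lines <- character()
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  epochs <- pipeline_stage("data", {
    if (!is.null(config$data$epochs_path)) {
      logf("reading epochs from %s", config$data$epochs_path)
      read_epochs(config$data$epochs_path)
    } else {
      logf("simulating %d subjects x %d blocks (%s, %d channels, SNR [%g, %g] dB)",
           config$data$n_subjects, config$data$n_blocks, config$data$preset,
           config$data$n_channels, config$data$snr_range[1],
           config$data$snr_range[2])
      generate_dataset(build_layout(config$data$preset),
                       n_subjects = config$data$n_subjects,
                       n_blocks = config$data$n_blocks,
                       duration = config$data$duration,
                       fs = config$data$fs,
                       n_channels = config$data$n_channels,
                       snr_range = config$data$snr_range,
                       seed = config$seed)
    }
  })
  if (!is.null(config$data$channels))
    epochs <- pipeline_stage("channel selection",
                             select_channels(epochs, config$data$channels))

  subjects <- unique(epochs$subject_ids)
  if (config$protocol == "subject_independent" && length(subjects) < 2)
    stop("configuration error: subject_independent protocol needs >= 2 ",
         "subjects, data has ", length(subjects))

  builder <- if (config$model$arch == "atten_ccnn") build_atten_ccnn
             else build_ccnn
  model_args <- config$model[c("se_ratio", "n_filters", "conv2_kernel",
                               "dense_width", "dropout", "l2")]
  default_bs <- if (config$protocol == "subject_independent") 256L else 16L
  tcfg <- train_config(
    learning_rate = config$train$learning_rate,
    epochs = config$train$epochs,
    batch_size = if (is.null(config$train$batch_size)) default_bs
                 else config$train$batch_size,
    momentum = config$train$momentum,
    seed = config$seed
  )
  pp <- config$preprocess

  report <- pipeline_stage("evaluation", {
    if (config$protocol == "subject_independent") {
      logf("LOSO over %d subjects (%s)", length(subjects), config$model$arch)
      loso_cv(epochs, builder, window_s = pp$window_s, train_cfg = tcfg,
              band = pp$band, filter_order = pp$filter_order,
              resolution = pp$resolution, feat_band = pp$feat_band,
              gaze_shift_s = config$gaze_shift_s, model_args = model_args)
    } else {
      logf("%d-fold CV per subject over %d subjects (%s)", config$k,
           length(subjects), config$model$arch)
      parts <- lapply(subjects, function(sid) {
        kfold_cv(subset_epochs(epochs, which(epochs$subject_ids == sid)),
                 builder, window_s = pp$window_s, train_cfg = tcfg,
                 k = config$k, band = pp$band,
                 filter_order = pp$filter_order,
                 resolution = pp$resolution, feat_band = pp$feat_band,
                 gaze_shift_s = config$gaze_shift_s, model_args = model_args)
      })
      folds <- do.call(rbind, lapply(seq_along(parts), function(i) {
        f <- parts[[i]]$folds
        f$fold <- f$fold + (i - 1L) * config$k
        f
      }))
      rpt <- new_eval_report(sprintf("subject-dependent (%d-fold)", config$k), folds,
                             pp$window_s, parts[[1]]$n_classes,
                             config$gaze_shift_s)
      rpt$per_subject <- data.frame(
        subject = subjects,
        accuracy = vapply(parts, function(p) p$mean_accuracy, numeric(1)),
        itr = vapply(parts, function(p) p$mean_itr, numeric(1)))
      rpt$predictions <- do.call(rbind, lapply(parts, `[[`, "predictions"))
      rpt
    }
  })
  logf("mean accuracy %.3f, mean ITR %.2f bits/min",
       report$mean_accuracy, report$mean_itr)

  if (!is.null(config$out_dir)) {
    pipeline_stage("artifacts", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_run_config(config, file.path(config$out_dir, "config.json"))
      jsonlite::write_json(
        list(protocol = report$protocol,
             window_s = report$window_s,
             n_classes = report$n_classes,
             mean_accuracy = report$mean_accuracy,
             sem_accuracy = report$sem_accuracy,
             mean_itr = report$mean_itr,
             itr_of_mean_accuracy = report$itr_of_mean_accuracy,
             folds = report$folds),
        file.path(config$out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.csv(report$predictions,
                       file.path(config$out_dir, "predictions.csv"),
                       row.names = FALSE)
      writeLines(log_lines, file.path(config$out_dir, "run.log"))
    })
    logf("artifacts written to %s", config$out_dir)
  }
  report
}
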
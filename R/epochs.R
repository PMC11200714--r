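#' Labelled EEG epoch container
#'
#' Bundles a trials x channels x samples array (microvolts) with per-trial
#' target labels, per-trial subject identifiers, the sampling rate and
#' channel names. All downstream steps (filtering, segmentation, feature
#' extraction, cross-validation) operate on this container.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]` in uV.
#' @param labels integer vector of 0-based target indices, one per trial.
#' @param subject_ids character or integer vector, one per trial.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `n_channels`.
#' @param n_classes number of targets encoded by `labels`; defaults to
#'   `max(labels) + 1`.
#'
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, subject_ids, fs, channel_names,
                       n_classes = NULL) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3-d array [trials x channels x samples]")
  n_trials <- dim(data)[1]
  if (length(labels) != n_trials)
    stop("labels length (", length(labels), ") != n_trials (", n_trials, ")")
  if (length(subject_ids) != n_trials)
    stop("subject_ids length != n_trials")
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length (", length(channel_names),
         ") != n_channels (", dim(data)[2], ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stop("data contains NaN/Inf")
  labels <- as.integer(labels)
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  if (any(labels < 0L) || any(labels >= n_classes))
    stop("labels must lie in [0, n_classes)")
  structure(
    list(data = data, labels = labels,
         subject_ids = as.character(subject_ids),
         fs = fs, channel_names = as.character(channel_names),
         n_classes = as.integer(n_classes)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("EEG epochs: %d trials x %d channels x %d samples ",
                     "@ %g Hz (%.2f s)\n"),
              d[1], d[2], d[3], x$fs, d[3] / x$fs))
  cat(sprintf("  %d classes, %d subjects (%s)\n", x$n_classes,
              length(unique(x$subject_ids)),
              paste(utils::head(unique(x$subject_ids), 6), collapse = ", ")))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Subset epochs by trial
#'
#' @param epochs an [eeg_epochs] object.
#' @param idx trial indices (1-based) to keep.
#' @return An [eeg_epochs] with the selected trials.
#' @export
subset_epochs <- function(epochs, idx) {
  eeg_epochs(epochs$data[idx, , , drop = FALSE],
             epochs$labels[idx], epochs$subject_ids[idx],
             epochs$fs, epochs$channel_names, epochs$n_classes)
}

#' Select channels by name
#'
#' @param epochs an [eeg_epochs] object.
#' @param channels character vector of channel names to keep, in the
#'   requested order.
#' @return An [eeg_epochs] restricted to the requested channels.
#' @export
select_channels <- function(epochs, channels) {
  pos <- match(channels, epochs$channel_names)
  if (anyNA(channels) || anyNA(pos))
    stop("unknown channel(s): ",
         paste(channels[is.na(pos)], collapse = ", "),
         "; available: ", paste(epochs$channel_names, collapse = ", "))
  eeg_epochs(epochs$data[, pos, , drop = FALSE],
             epochs$labels, epochs$subject_ids,
             epochs$fs, epochs$channel_names[pos], epochs$n_classes)
}

EPOCHS_FORMAT_VERSION <- 1L

#' Read and write the on-disk epoch container
#'
#' Epochs are stored as a versioned serialized container holding the fields
#' `data`, `labels`, `subject_ids`, `fs`, `channel_names`, `n_classes` and a
#' `format_version` stamp. Reading validates every field and fails with the
#' name of the first missing one, so a truncated or foreign file is rejected
#' rather than silently partially loaded.
#'
#' @param epochs an [eeg_epochs] object.
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   [eeg_epochs] object identical to the one written.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  payload <- unclass(epochs)
  payload$format_version <- EPOCHS_FORMAT_VERSION
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("cannot parse epoch container ",
                                               path, ": ", conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$format_version))
    stop("not an epoch container (missing field: format_version)")
  if (payload$format_version > EPOCHS_FORMAT_VERSION)
    stop("epoch container version ", payload$format_version,
         " is newer than supported version ", EPOCHS_FORMAT_VERSION)
  for (field in c("data", "labels", "subject_ids", "fs", "channel_names"))
    if (is.null(payload[[field]]))
      stop("epoch container missing field: ", field)
  eeg_epochs(payload$data, payload$labels, payload$subject_ids,
             payload$fs, payload$channel_names, payload$n_classes)
}
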
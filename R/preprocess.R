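#' Zero-phase Butterworth band-pass filtering
#'
#' Applies a Butterworth band-pass filter forward and backward
#' (`signal::filtfilt`) to every trial and channel. The forward-backward
#' scheme has zero phase response, which matters here because the downstream
#' complex-spectrum features encode phase; the price is that the effective
#' attenuation is that of the squared magnitude response (2 x `order` poles).
#'
#' @param epochs an [eeg_epochs] object.
#' @param band length-2 numeric `(f_lo, f_hi)` in Hz; default `c(3, 45)`
#'   covers the stimulus fundamentals of both built-in layouts and at least
#'   two harmonics.
#' @param order filter order of the underlying design; default 4.
#' @return An [eeg_epochs] of the same shape, filtered.
#' @export
bandpass_filter <- function(epochs, band = c(3, 45), order = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"), length(band) == 2L)
  nyq <- epochs$fs / 2
  if (band[1] <= 0) stop("lower band edge must be > 0 (got ", band[1], ")")
  if (band[2] >= nyq) stop("upper band edge ", band[2],
                           " Hz is at or above Nyquist (", nyq, " Hz)")
  if (band[1] >= band[2]) stop("band edges must satisfy f_lo < f_hi")
  flt <- signal::butter(order, band / nyq, type = "pass")
  d <- epochs$data
  for (i in seq_len(dim(d)[1]))
    for (c in seq_len(dim(d)[2]))
      d[i, c, ] <- signal::filtfilt(flt, d[i, c, ])
  epochs$data <- d
  epochs
}

#' Split trials into non-overlapping segments
#'
#' Each trial of `n_samples` yields `floor(n_samples / n_win)` consecutive
#' non-overlapping windows of `n_win = floor(window_s * fs)` samples; any
#' leftover tail is discarded. Segments inherit the label and subject id of
#' their parent trial.
#'
#' @param epochs an [eeg_epochs] object.
#' @param window_s window length in seconds.
#' @return An [eeg_epochs] whose "trials" are the segments.
#' @export
segment_epochs <- function(epochs, window_s) {
  stopifnot(inherits(epochs, "eeg_epochs"), window_s > 0)
  n_win <- floor(window_s * epochs$fs)
  if (n_win < 1) stop("window shorter than one sample")
  n_samples <- dim(epochs$data)[3]
  if (n_win > n_samples)
    stop("window (", n_win, " samples) longer than trial (", n_samples, ")")
  k <- n_samples %/% n_win
  n_trials <- dim(epochs$data)[1]
  n_channels <- dim(epochs$data)[2]

  out <- array(0, dim = c(n_trials * k, n_channels, n_win))
  seg <- 0L
  for (i in seq_len(n_trials)) {
    for (w in seq_len(k)) {
      seg <- seg + 1L
      out[seg, , ] <- epochs$data[i, , ((w - 1) * n_win + 1):(w * n_win)]
    }
  }
  eeg_epochs(out,
             rep(epochs$labels, each = k),
             rep(epochs$subject_ids, each = k),
             epochs$fs, epochs$channel_names, epochs$n_classes)
}

#' Complex spectrum of a single segment
#'
#' Computes, per channel, the un-normalized DFT of the zero-padded signal at
#' `NFFT = round(fs / resolution)` points, keeps the bins whose frequency
#' lies in `[f_lo, f_hi]`, and concatenates the real parts followed by the
#' imaginary parts along the feature axis. Zero-padding interpolates the
#' spectrum to the requested resolution; it adds no information but places
#' every stimulus frequency close to a bin center. The layout — amplitude
#' and phase jointly encoded as `[Re | Im]` — is exactly what the network
#' consumes.
#'
#' @param segment numeric matrix `[n_channels x n_samples]` (a vector is
#'   treated as one channel).
#' @param fs sampling rate in Hz.
#' @param resolution frequency-grid step in Hz; default 0.25.
#' @param band length-2 numeric `(f_lo, f_hi)` in Hz, inclusive; default
#'   `c(3, 35)`.
#' @return A list with `matrix` (`[n_channels x Nsp]`, `Nsp = 2 * n_bins`),
#'   `freq_grid`, `resolution` and `band`.
#' @export
complex_spectrum <- function(segment, fs, resolution = 0.25, band = c(3, 35)) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment)
  if (band[1] >= band[2] || band[1] <= 0 || band[2] >= fs / 2)
    stop("band must satisfy 0 < f_lo < f_hi < fs/2")
  nfft <- round(fs / resolution)
  if (nfft < n)
    stop("resolution too coarse: NFFT = ", nfft, " < n_samples = ", n)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  keep <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  if (length(keep) == 0) stop("empty band: no DFT bins in [",
                              band[1], ", ", band[2], "] Hz")
  padded <- cbind(segment, matrix(0, nrow(segment), nfft - n))
  spec <- t(apply(padded, 1, stats::fft))
  if (nrow(segment) == 1L) spec <- matrix(spec, nrow = 1)
  sel <- spec[, keep, drop = FALSE]
  list(matrix = cbind(Re(sel), Im(sel)),
       freq_grid = freqs[keep],
       resolution = resolution,
       band = band)
}

#' Complex-spectrum features for a whole epoch set
#'
#' Vectorized application of [complex_spectrum()] to every segment of an
#' epoch container, carrying labels and subject ids through.
#'
#' @param epochs an [eeg_epochs] object (typically already segmented).
#' @param resolution,band see [complex_spectrum()].
#' @return An object of class `spectrum_features`: list with `features`
#'   (array `[n_segments, n_channels, Nsp]`), `freq_grid`, `resolution`,
#'   `band`, `labels`, `subject_ids`, `n_classes`, `fs`, `channel_names`
#'   and `window_s`.
#' @export
spectrum_features <- function(epochs, resolution = 0.25, band = c(3, 35)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  n_seg <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  fs <- epochs$fs
  nfft <- round(fs / resolution)
  if (nfft < n_samp)
    stop("resolution too coarse: NFFT = ", nfft, " < n_samples = ", n_samp)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  keep <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  if (length(keep) == 0) stop("empty band")
  nb <- length(keep)

  # One big FFT call: stack all (segment, channel) series as columns.
  flat <- matrix(0, nfft, n_seg * n_ch)
  flat[seq_len(n_samp), ] <- t(matrix(epochs$data, n_seg * n_ch, n_samp))
  spec <- stats::mvfft(flat)[keep, , drop = FALSE]

  feats <- array(0, dim = c(n_seg, n_ch, 2L * nb))
  feats[, , seq_len(nb)] <- array(t(Re(spec)), dim = c(n_seg, n_ch, nb))
  feats[, , nb + seq_len(nb)] <- array(t(Im(spec)), dim = c(n_seg, n_ch, nb))

  structure(
    list(features = feats, freq_grid = freqs[keep],
         resolution = resolution, band = band,
         labels = epochs$labels, subject_ids = epochs$subject_ids,
         n_classes = epochs$n_classes, fs = fs,
         channel_names = epochs$channel_names,
         window_s = n_samp / fs),
    class = "spectrum_features"
  )
}

#' @export
print.spectrum_features <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("Complex-spectrum features: %d segments x %d channels x %d (Nsp)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %d bins in [%g, %g] Hz at %g Hz resolution, window %.2g s\n",
              length(x$freq_grid), x$band[1], x$band[2], x$resolution,
              x$window_s))
  invisible(x)
}

#' Subset features by segment
#'
#' @param feats a [spectrum_features] object.
#' @param idx segment indices (1-based).
#' @return A [spectrum_features] restricted to `idx`.
#' @export
subset_features <- function(feats, idx) {
  feats$features <- feats$features[idx, , , drop = FALSE]
  feats$labels <- feats$labels[idx]
  feats$subject_ids <- feats$subject_ids[idx]
  feats
}
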
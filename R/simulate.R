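# Synthetic JFPM-SSVEP generator: per-target harmonic series plus 1/f
# background noise, with per-subject amplitude, SNR and latency variability.

SYNTH_CHANNELS <- c("Oz", "O1", "O2", "POz", "PO3", "PO4", "PO5", "PO6")

synth_channel_names <- function(n_channels) {
  if (n_channels <= length(SYNTH_CHANNELS)) return(SYNTH_CHANNELS[seq_len(n_channels)])
  c(SYNTH_CHANNELS, sprintf("EXT%d", seq_len(n_channels - length(SYNTH_CHANNELS))))
}

# Electrode placement model: Oz carries the strongest SSVEP, with a linear
# 10% roll-off per position in the montage order above (floor at 0.1).
synth_channel_scales <- function(n_channels) {
  pmax(1 - 0.1 * (seq_len(n_channels) - 1), 0.1)
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Per-subject response model for the synthetic generator
#'
#' Captures the between-subject variability the decoder has to cope with:
#' harmonic amplitudes (uV), a common response-latency offset (drawn once per
#' subject from `N(0, latency_jitter_sd)`), and the signal-to-noise ratio of
#' the recording.
#'
#' @param amplitude_per_harmonic positive amplitudes in uV, one per harmonic;
#'   default `c(1, 0.5, 0.25)` reflects the usual SSVEP harmonic roll-off.
#' @param latency_jitter_sd standard deviation (s) of the subject's common
#'   response latency; default 0.010 s.
#' @param snr_db signal-to-noise ratio in dB (signal power of the strongest
#'   channel vs. background-noise power in the 3-35 Hz band).
#' @param seed integer seed; fixes the subject's latency draw and the noise
#'   stream when trials are generated stand-alone.
#'
#' @return An object of class `ssvep_subject`.
#' @export
subject_model <- function(amplitude_per_harmonic = c(1, 0.5, 0.25),
                          latency_jitter_sd = 0.010,
                          snr_db = 10, seed = 1L) {
  stopifnot(all(amplitude_per_harmonic > 0), is.finite(snr_db),
            latency_jitter_sd >= 0)
  latency_s <- with_preserved_rng({
    set.seed(as.integer(seed))
    stats::rnorm(1, 0, latency_jitter_sd)
  })
  structure(
    list(amplitude_per_harmonic = as.numeric(amplitude_per_harmonic),
         latency_jitter_sd = latency_jitter_sd,
         latency_s = latency_s,
         snr_db = snr_db, seed = as.integer(seed)),
    class = "ssvep_subject"
  )
}

#' 1/f (pink) background noise
#'
#' White Gaussian noise spectrally shaped by a 1/f amplitude envelope for
#' f >= 1 Hz (flat below 1 Hz, zero DC), the standard stand-in for the
#' broadband background EEG spectrum.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of length `n`, unit-free scale.
#' @export
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freqs <- seq(0, n - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided -> physical frequency
  env <- ifelse(freqs >= 1, 1 / freqs, 1)
  env[1] <- 0
  Re(stats::fft(spec * env, inverse = TRUE)) / n
}

band_power <- function(x, fs, band = c(3, 35)) {
  n <- length(x)
  spec <- stats::fft(x)
  freqs <- seq(0, n - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  mean(Re(stats::fft(spec * keep, inverse = TRUE) / n)^2)
}

#' Generate one synthetic SSVEP trial
#'
#' The noise-free response is a sum of harmonics of the target frequency,
#' `sum_h A_h sin(2*pi*h*f*(t + tau) + h*phi)`, so that the JFPM phase and
#' the subject's latency `tau` act as a common time shift across harmonics.
#' Channel k is scaled by the electrode placement model (Oz strongest).
#' Background noise is a 4:1 power mixture of 1/f and white noise, identical
#' in level across channels and scaled so that the strongest channel attains
#' the subject's `snr_db` (signal power vs. noise power in 3-35 Hz).
#' Harmonics at or above Nyquist are excluded with a message.
#'
#' @param layout an `ssvep_layout` from [build_layout()].
#' @param target 1-based target index into `layout$targets`.
#' @param duration trial length in seconds.
#' @param fs sampling rate in Hz.
#' @param subject an [subject_model()] object.
#' @param n_channels number of EEG channels (Oz first).
#' @param n_harmonics harmonics to synthesize (capped below Nyquist).
#' @param seed optional integer; when given the trial is a pure function of
#'   its arguments, when `NULL` the current RNG stream is consumed (used by
#'   [generate_dataset()]).
#'
#' @return Numeric matrix `[n_channels x n_samples]` in uV.
#' @export
generate_trial <- function(layout, target, duration, fs, subject,
                           n_channels = 3, n_harmonics = 3, seed = NULL) {
  stopifnot(inherits(layout, "ssvep_layout"), inherits(subject, "ssvep_subject"))
  n_samples <- round(duration * fs)
  if (n_samples < 1) stop("duration * fs must be at least one sample")
  if (target < 1 || target > n_targets(layout)) stop("target out of range")
  if (!is.null(seed)) set.seed(as.integer(seed))

  f <- layout$targets$frequency_hz[target]
  phi <- layout$targets$phase_rad[target]
  amps <- subject$amplitude_per_harmonic[seq_len(min(n_harmonics,
          length(subject$amplitude_per_harmonic)))]
  h_all <- seq_along(amps)
  ok <- h_all * f < fs / 2
  if (!all(ok))
    message(sprintf("excluding harmonic(s) %s of %.2f Hz at or above Nyquist (fs = %g)",
                    paste(h_all[!ok], collapse = ","), f, fs))
  h <- h_all[ok]; amps <- amps[ok]

  t <- (seq_len(n_samples) - 1) / fs + subject$latency_s
  s <- rep(0, n_samples)
  for (k in seq_along(h))
    s <- s + amps[k] * sin(2 * pi * h[k] * f * t + h[k] * phi)

  scales <- synth_channel_scales(n_channels)
  p_sig <- mean((scales[1] * s)^2)

  out <- matrix(0, n_channels, n_samples)
  for (c in seq_len(n_channels)) {
    pink <- pink_noise(n_samples, fs)
    pink_sd <- stats::sd(pink)
    if (pink_sd > 0) pink <- pink / pink_sd
    noise <- sqrt(0.8) * pink + sqrt(0.2) * stats::rnorm(n_samples)
    p_noise <- band_power(noise, fs)
    gain <- if (p_noise > 0) sqrt(p_sig / (p_noise * 10^(subject$snr_db / 10))) else 0
    out[c, ] <- scales[c] * s + gain * noise
  }
  out
}

#' Generate a full multi-subject synthetic dataset
#'
#' Emulates the block design of SSVEP speller experiments: every
#' (subject, block) pair contains each target exactly once, in randomized
#' order. Per-subject response models (harmonic amplitude gain, latency,
#' SNR) are drawn reproducibly from `seed`.
#'
#' @param layout an `ssvep_layout` from [build_layout()].
#' @param n_subjects,n_blocks experiment size; all counts >= 1.
#' @param duration trial length in seconds (stimulation period).
#' @param fs sampling rate in Hz.
#' @param n_channels number of channels (Oz first; 1, 3 or 8 are typical).
#' @param snr_range length-2 numeric; per-subject SNR drawn uniformly from
#'   this range (dB). A single number fixes the SNR for all subjects.
#' @param seed integer master seed; the whole dataset is a pure function of
#'   the arguments.
#' @param n_harmonics harmonics per target.
#' @param latency_jitter_sd per-subject latency sd in seconds.
#'
#' @return An [eeg_epochs] object with `n_subjects * n_blocks * n_targets`
#'   trials and subject ids `"S01", "S02", ...`.
#' @export
generate_dataset <- function(layout, n_subjects, n_blocks, duration = 4,
                             fs = 256, n_channels = 3,
                             snr_range = c(0, 10), seed = 1L,
                             n_harmonics = 3, latency_jitter_sd = 0.010) {
  stopifnot(n_subjects >= 1, n_blocks >= 1, duration > 0)
  if (length(snr_range) == 1L) snr_range <- rep(snr_range, 2)
  nt <- n_targets(layout)
  n_samples <- round(duration * fs)
  n_trials <- n_subjects * n_blocks * nt

  set.seed(as.integer(seed))
  data <- array(0, dim = c(n_trials, n_channels, n_samples))
  labels <- integer(n_trials)
  subject_ids <- character(n_trials)

  trial <- 0L
  for (s in seq_len(n_subjects)) {
    gain <- stats::runif(1, 0.8, 1.2)
    snr <- stats::runif(1, snr_range[1], snr_range[2])
    subj <- subject_model(
      amplitude_per_harmonic = gain * c(1, 0.5, 0.25)[seq_len(n_harmonics)],
      latency_jitter_sd = latency_jitter_sd,
      snr_db = snr,
      seed = sample.int(.Machine$integer.max, 1)
    )
    sid <- sprintf("S%02d", s)
    for (b in seq_len(n_blocks)) {
      for (tg in sample.int(nt)) {
        trial <- trial + 1L
        data[trial, , ] <- generate_trial(layout, tg, duration, fs, subj,
                                          n_channels, n_harmonics, seed = NULL)
        labels[trial] <- tg - 1L
        subject_ids[trial] <- sid
      }
    }
  }
  eeg_epochs(data, labels, subject_ids, fs,
             synth_channel_names(n_channels), n_classes = nt)
}
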
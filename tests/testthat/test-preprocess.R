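sine_epochs <- function(freq, fs = 256, dur = 2, amp = 1) {
  n <- dur * fs
  x <- amp * sin(2 * pi * freq * (0:(n - 1)) / fs)
  eeg_epochs(array(x, dim = c(1, 1, n)), labels = 0L, subject_ids = "S01",
             fs = fs, channel_names = "Oz", n_classes = 2L)
}

# magnitude response of the designed digital filter at frequency f;
# forward-backward filtering applies it twice
butter_gain <- function(band, order, fs, f) {
  flt <- signal::butter(order, band / (fs / 2), type = "pass")
  z <- exp(1i * 2 * pi * f / fs)
  h <- sum(flt$b * z^(-(seq_along(flt$b) - 1))) /
    sum(flt$a * z^(-(seq_along(flt$a) - 1)))
  Mod(h)^2
}

test_that("band-pass keeps in-band amplitude and rejects out-of-band", {
  fs <- 256
  ep <- sine_epochs(10, fs = fs)
  out <- bandpass_filter(ep, band = c(3, 45), order = 4)
  mid <- 150:360  # away from edge transients
  ratio <- max(abs(out$data[1, 1, mid])) / 1
  expect_equal(ratio, butter_gain(c(3, 45), 4, fs, 10), tolerance = 0.005)
  expect_gt(ratio, 0.98)  # within 2% of unity in the passband

  ep100 <- sine_epochs(100, fs = fs)
  out100 <- bandpass_filter(ep100, band = c(3, 45), order = 4)
  att <- max(abs(out100$data[1, 1, mid]))
  expect_lt(att, 10^(-20 / 20))  # >= 20 dB down
})

test_that("filtering is zero-phase and maps zeros to zeros", {
  fs <- 256
  ep <- sine_epochs(10, fs = fs)
  out <- bandpass_filter(ep, band = c(3, 45))
  mid <- 150:360
  # zero phase: in-band component unshifted -> correlation ~ 1 at lag 0
  expect_gt(cor(ep$data[1, 1, mid], out$data[1, 1, mid]), 0.9999)

  zep <- eeg_epochs(array(0, dim = c(2, 1, 256)), labels = c(0L, 1L),
                    subject_ids = c("a", "b"), fs = fs,
                    channel_names = "Oz")
  zout <- bandpass_filter(zep)
  expect_true(all(zout$data == 0))
})

test_that("band edges are validated against Nyquist", {
  ep <- sine_epochs(10)
  expect_error(bandpass_filter(ep, band = c(3, 130)), "Nyquist")
  expect_error(bandpass_filter(ep, band = c(0, 45)), "lower band edge")
  expect_error(bandpass_filter(ep, band = c(45, 3)), "f_lo < f_hi")
})

test_that("segmentation yields floor(n/n_win) inherited segments", {
  fs <- 256
  mk <- function(dur) {
    n <- round(dur * fs)
    eeg_epochs(array(rnorm(2 * 2 * n), dim = c(2, 2, n)),
               labels = c(0L, 1L), subject_ids = c("S01", "S02"),
               fs = fs, channel_names = c("Oz", "O1"))
  }
  s3 <- segment_epochs(mk(3), 1.0)
  expect_equal(dim(s3$data), c(6, 2, 256))
  expect_equal(s3$labels, rep(c(0L, 1L), each = 3))
  expect_equal(s3$subject_ids, rep(c("S01", "S02"), each = 3))

  # 4 s at 256 Hz with 0.4 s windows: floor(1024 / 102) = 10 segments
  s04 <- segment_epochs(mk(4), 0.4)
  expect_equal(dim(s04$data), c(20, 2, 102))

  ep1 <- mk(1)
  s1 <- segment_epochs(ep1, 1.0)
  expect_identical(s1$data, ep1$data)

  expect_error(segment_epochs(ep1, 2.0), "longer than trial")
})

test_that("segments reassemble into the trial when it divides evenly", {
  fs <- 128
  n <- 4 * fs
  ep <- eeg_epochs(array(rnorm(n), dim = c(1, 1, n)), 0L, "S01", fs, "Oz",
                   n_classes = 2L)
  segs <- segment_epochs(ep, 1.0)
  rebuilt <- as.vector(t(segs$data[, 1, ]))
  expect_identical(rebuilt, ep$data[1, 1, ])
})

test_that("complex spectrum separates cosine and sine into Re and Im", {
  fs <- 256
  t <- (0:255) / fs
  cs <- complex_spectrum(cos(2 * pi * 8 * t), fs, resolution = 0.25,
                         band = c(3, 35))
  nb <- length(cs$freq_grid)
  bin <- which(cs$freq_grid == 8)
  re <- cs$matrix[1, seq_len(nb)]
  im <- cs$matrix[1, nb + seq_len(nb)]
  expect_equal(which.max(re), bin)
  expect_lt(abs(im[bin]), 1e-6 * abs(re[bin]))

  cs2 <- complex_spectrum(sin(2 * pi * 8 * t), fs)
  re2 <- cs2$matrix[1, seq_len(nb)]
  im2 <- cs2$matrix[1, nb + seq_len(nb)]
  expect_gt(abs(im2[bin]), 1e6 * abs(re2[bin]))
})

test_that("complex spectrum matches a brute-force DFT", {
  set.seed(31)
  x <- matrix(rnorm(3 * 256), 3, 256)
  fs <- 256
  cs <- complex_spectrum(x, fs, resolution = 0.25, band = c(3, 35))
  nb <- length(cs$freq_grid)
  expect_equal(nb, 129L)  # 3..35 Hz inclusive at 0.25 Hz
  expect_equal(ncol(cs$matrix), 258L)
  # O(N^2) DFT at the retained bin frequencies, same un-normalized convention
  nfft <- round(fs / 0.25)
  n <- ncol(x)
  for (ch in 1:3) {
    ref <- vapply(cs$freq_grid, function(f) {
      sum(x[ch, ] * exp(-2i * pi * f * (0:(n - 1)) / fs))
    }, complex(1))
    expect_lt(max(abs(cs$matrix[ch, seq_len(nb)] - Re(ref))), 1e-8)
    expect_lt(max(abs(cs$matrix[ch, nb + seq_len(nb)] - Im(ref))), 1e-8)
  }
})

test_that("complex spectrum is linear and band-limited in energy", {
  set.seed(32)
  fs <- 128
  x <- matrix(rnorm(2 * 128), 2, 128)
  y <- matrix(rnorm(2 * 128), 2, 128)
  a <- 1.7; b <- -0.4
  cs_sum <- complex_spectrum(a * x + b * y, fs)
  cs_x <- complex_spectrum(x, fs)
  cs_y <- complex_spectrum(y, fs)
  expect_equal(cs_sum$matrix, a * cs_x$matrix + b * cs_y$matrix,
               tolerance = 1e-10)
  # Parseval-style bound: retained-band energy <= total energy
  full <- complex_spectrum(x, fs, resolution = 1, band = c(1, 63))
  nfft <- round(fs / 1)
  for (ch in 1:2) {
    nb <- length(full$freq_grid)
    band_energy <- 2 * sum(full$matrix[ch, ]^2) / nfft^2  # one-sided
    expect_lte(band_energy, sum(x[ch, ]^2) * (1 + 1e-12))
  }
})

test_that("batch features agree with the single-segment transform", {
  set.seed(33)
  ep <- generate_dataset(build_layout("dataset2_12class"), 1, 1, 1, 256, 3,
                         snr_range = 10, seed = 5)
  feats <- spectrum_features(ep)
  i <- 7
  single <- complex_spectrum(ep$data[i, , ], 256)
  expect_equal(feats$features[i, , ], single$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(feats$freq_grid, single$freq_grid)
  expect_error(complex_spectrum(ep$data[1, , ], 256, band = c(30, 20)),
               "band")
})
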
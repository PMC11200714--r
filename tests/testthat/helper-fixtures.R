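# Shared fixtures, built lazily and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a model small enough for finite-difference checks and fast structural tests
tiny_config <- function(n_channels = 2, n_classes = 3, dropout = 0, l2 = 0) {
  model_config(n_channels = n_channels, n_features = 24,
               n_classes = n_classes,
               n_filters = 4, conv2_kernel = 5, dense_width = 6,
               dropout = dropout, se_ratio = 2, l2 = l2)
}

tiny_batch <- function(n = 3, n_channels = 2, n_features = 24, seed = 99) {
  set.seed(seed)
  array(rnorm(n * n_channels * n_features), dim = c(n, n_channels, n_features))
}

# 1 subject x 10 blocks of clean 12-class data: the workhorse for training
# and subject-dependent protocol tests
clean_subject_epochs <- function() {
  fixture("clean_subject", function() {
    generate_dataset(build_layout("dataset2_12class"), n_subjects = 1,
                     n_blocks = 10, duration = 1, fs = 256, n_channels = 3,
                     snr_range = 20, seed = 11)
  })
}

clean_subject_features <- function() {
  fixture("clean_subject_feats", function() {
    spectrum_features(segment_epochs(bandpass_filter(clean_subject_epochs()), 1))
  })
}

# an easily separable two-class feature set for overfit/determinism tests
toy_features <- function(n_per_class = 100) {
  set.seed(4242)
  n <- 2 * n_per_class
  feats <- array(rnorm(n * 2 * 24, sd = 0.1), dim = c(n, 2, 24))
  labs <- rep(0:1, each = n_per_class)
  feats[labs == 0, , 5] <- feats[labs == 0, , 5] + 3
  feats[labs == 1, , 15] <- feats[labs == 1, , 15] + 3
  structure(list(features = feats, freq_grid = seq_len(12),
                 resolution = 1, band = c(1, 12), labels = labs,
                 subject_ids = rep("S01", n), n_classes = 2L, fs = 256,
                 channel_names = c("Oz", "O1"), window_s = 1),
            class = "spectrum_features")
}

# independent parameter-count oracle: plain layer-by-layer arithmetic,
# written against the architecture description, not the builder code
oracle_param_count <- function(nch, nsp, classes, f = 32, k = 20, dense = 144,
                               r = 4, atten = TRUE) {
  conv1 <- f * nch + f
  bn <- 2 * f
  se <- (f %/% r) * f + (f %/% r) + f * (f %/% r) + f
  conv2 <- f * f * k + f
  if (atten) {
    conv1 + bn + se + conv2 + bn + se +
      (dense * f * nsp + dense) + (classes * dense + classes)
  } else {
    conv1 + bn + conv2 + bn + (classes * f * nsp + classes)
  }
}
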
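# independent textbook evaluation of the ITR formula
itr_ref <- function(K, P, T_s) {
  term <- log2(K) +
    (if (P > 0) P * log2(P) else 0) +
    (if (P < 1) (1 - P) * log2((1 - P) / (K - 1)) else 0)
  60 * term / T_s
}

test_that("chance-level accuracy gives exactly zero ITR", {
  for (K in c(2, 12, 40)) {
    expect_identical(itr(K, 1 / K, 1.55), 0)
  }
})

test_that("perfect accuracy gives the closed-form ceiling", {
  expect_equal(itr(40, 1, 1.55), 60 * log2(40) / 1.55, tolerance = 1e-12)
  expect_equal(itr(40, 1, 1.55), 206.0078, tolerance = 1e-4)
  expect_equal(itr(12, 1, 1.55), 60 * log2(12) / 1.55, tolerance = 1e-12)
})

test_that("ITR matches independent evaluation and is clipped below chance", {
  expect_equal(itr(12, 0.8, 1.55), itr_ref(12, 0.8, 1.55), tolerance = 1e-10)
  expect_equal(itr(12, 0.8, 1.55), 84.0367, tolerance = 1e-3)
  expect_message(v <- itr(12, 0.01, 1.55), "clipped")
  expect_identical(v, 0)
})

test_that("ITR increases with accuracy and decreases with selection time", {
  for (K in c(12, 40)) {
    ps <- seq(1 / K, 1, length.out = 25)
    vals <- suppressMessages(itr(K, ps, 1.55))
    expect_true(all(diff(vals) >= 0))
    ts <- seq(0.75, 3, by = 0.25)
    vals_t <- vapply(ts, function(tt) itr(K, 0.8, tt), numeric(1))
    expect_true(all(diff(vals_t) < 0))
  }
})

test_that("paired comparison reproduces the textbook paired t-test", {
  set.seed(50)
  a <- runif(8, 0.4, 0.9)
  b <- a + rnorm(8, 0.03, 0.05)
  res <- paired_compare(a, b)
  # textbook formula, computed from scratch
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * pt(-abs(t_ref), length(d) - 1)
  expect_lt(abs(res$t - t_ref), 1e-10)
  expect_lt(abs(res$p_value - p_ref), 1e-10)
  expect_equal(res$df, 7)
})

test_that("degenerate paired comparisons are banded sensibly", {
  x <- c(0.5, 0.6, 0.7, 0.8, 0.6, 0.7)
  same <- paired_compare(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$band, "ns")
  shift <- paired_compare(x + 0.1, x)
  expect_equal(shift$p_value, 0)
  expect_equal(shift$band, "***")
  expect_gt(shift$mean_diff, 0)
  expect_error(paired_compare(x, x[1:3]), "differ in length")
})

test_that("significance bands follow the reporting convention", {
  # construct difference vectors with known p-values via the t quantile
  band_of <- function(p) {
    if (p >= 0.05) "ns" else if (p >= 0.01) "*"
    else if (p >= 0.001) "**" else "***"
  }
  set.seed(51)
  for (i in 1:5) {
    a <- runif(6); b <- a + rnorm(6, sd = 0.1)
    res <- paired_compare(a, b)
    expect_equal(res$band, band_of(res$p_value))
  }
})

test_that("10-fold partitions are disjoint, exhaustive and seeded", {
  ep <- clean_subject_epochs()
  # partition logic: 40 segments into k = 10 folds of 4
  set.seed(1)
  fold_of <- sample(rep(seq_len(10), length.out = 40))
  expect_equal(as.vector(table(fold_of)), rep(4L, 10))

  # through the public interface: tiny training so the protocol test is fast
  tc <- train_config(epochs = 2, batch_size = 16, seed = 5)
  rpt <- kfold_cv(ep, build_ccnn, window_s = 1, train_cfg = tc, k = 10)
  expect_equal(nrow(rpt$folds), 10L)
  expect_equal(sort(rpt$predictions$segment), seq_len(120))
  expect_equal(as.vector(table(rpt$predictions$fold)), rep(12L, 10))
  rpt2 <- kfold_cv(ep, build_ccnn, window_s = 1, train_cfg = tc, k = 10)
  expect_identical(rpt$folds, rpt2$folds)

  expect_error(kfold_cv(subset_epochs(ep, 1:5), build_ccnn, window_s = 1,
                        train_cfg = tc, k = 10), "fewer segments")
})

test_that("LOSO folds never share subjects between train and test", {
  lay <- build_layout("dataset2_12class")
  ep <- generate_dataset(lay, n_subjects = 3, n_blocks = 1, duration = 1,
                         fs = 128, n_channels = 2, snr_range = 15, seed = 61)
  tc <- train_config(epochs = 2, batch_size = 64, seed = 6)
  rpt <- loso_cv(ep, build_ccnn, window_s = 1, train_cfg = tc)
  expect_equal(nrow(rpt$folds), 3L)
  expect_setequal(rpt$folds$subject, unique(ep$subject_ids))
  # every segment of the held-out subject is tested in exactly that fold
  for (i in 1:3) {
    tested <- rpt$predictions[rpt$predictions$fold == i, ]
    expect_equal(unique(tested$subject), rpt$folds$subject[i])
    expect_equal(nrow(tested), rpt$folds$n_test[i])
  }
  single <- subset_epochs(ep, which(ep$subject_ids == "S01"))
  expect_error(loso_cv(single, build_ccnn, window_s = 1, train_cfg = tc),
               "kfold_cv")
  expect_error(kfold_cv(ep, build_ccnn, window_s = 1, train_cfg = tc),
               "one subject")
})

test_that("LOSO and subject-dependent accuracy agree on easy data", {
  # at high SNR both protocols should saturate; the subject-independent
  # penalty on this generator is bounded (sanity band, not an effect claim)
  lay <- build_layout("dataset2_12class")
  ep <- generate_dataset(lay, n_subjects = 2, n_blocks = 3, duration = 1,
                         fs = 256, n_channels = 3, snr_range = 20, seed = 71)
  tc <- train_config(epochs = 15, batch_size = 16, seed = 72)
  loso <- loso_cv(ep, build_atten_ccnn, window_s = 1,
                  train_cfg = train_config(epochs = 15, batch_size = 64,
                                           seed = 72))
  s1 <- subset_epochs(ep, which(ep$subject_ids == "S01"))
  dep <- kfold_cv(s1, build_atten_ccnn, window_s = 1, train_cfg = tc, k = 5)
  expect_lte(abs(loso$mean_accuracy - dep$mean_accuracy), 0.10)
})
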
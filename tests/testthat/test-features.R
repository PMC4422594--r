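test_that("PSD locates a pure tone and vanishes for a zero signal", {
  zero <- matrix(0, 32, 2)
  psd <- window_psd(zero, 128)
  expect_true(all(as.matrix(psd[, -1]) == 0))
  t <- (0:31) / 128
  tone <- matrix(sin(2 * pi * 10 * t), ncol = 1)
  psd1 <- window_psd(tone, 128)
  expect_equal(psd1$freq[which.max(psd1[[2]])], 10)
  expect_true(all(psd1[[2]] >= 0))
  expect_error(window_psd(tone, 128, grid = 0), "grid")
  expect_error(window_psd(tone[1, , drop = FALSE], 128), "2 samples")
})

test_that("white-noise PSD is flat in expectation over many windows", {
  set.seed(9)
  rate <- 128
  rec <- eeg_recording(matrix(rnorm(32 * 1000), ncol = 1), rate, "A")
  ep <- eeg_segment(rec)
  arr <- array(unlist(ep$data), c(32, 1, nrow(ep)))
  psd <- apply(psd_matrix(arr, rate), 1, mean)
  freq <- (seq_along(psd) - 1) * 0.5
  mid <- psd[freq >= 4 & freq <= 50]
  expect_lt(max(mid) / mean(mid), 1.15)
  expect_gt(min(mid) / mean(mid), 0.85)
})

test_that("default montage and bands give exactly 84 ordered features", {
  cfg <- synth_config(session_length = 2, seed = 1)
  feats <- band_power_features(eeg_segment(simulate_session(cfg, "neutral")))
  expect_equal(ncol(feats) - 1, 84)
  expect_equal(names(feats)[2], "AF3_delta")
  expect_equal(names(feats)[8], "F7_delta")           # montage-major order
  expect_equal(names(feats)[ncol(feats)], "AF4_gamma")
  expect_equal(names(feats)[-1], feature_names())
  # generic montage/band count invariant
  rec <- eeg_recording(matrix(rnorm(128 * 2 * 3), ncol = 3), 128,
                       c("A", "B", "C"))
  two_bands <- tibble::tibble(band = c("lo", "hi"), low = c(1, 20),
                              high = c(20, 50))
  f2 <- band_power_features(eeg_segment(rec), bands = two_bands)
  expect_equal(ncol(f2) - 1, 6)
})

test_that("a 10 Hz tone on O1 maximises the (O1, alpha) raw feature", {
  set.seed(2)
  rate <- 128
  n <- rate * 10
  x <- matrix(rnorm(n * 14, sd = 0.5), ncol = 14)
  x[, 7] <- x[, 7] + 3 * sin(2 * pi * 10 * (0:(n - 1)) / rate)  # O1
  rec <- eeg_recording(x, rate)
  feats <- band_power_features(eeg_segment(rec), transform = "raw")
  means <- colMeans(feats[, -1])
  expect_equal(names(which.max(means)), "O1_alpha")
})

test_that("six bands partition the PSD mass over [0.5, 50] Hz", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(128), ncol = 1), 128, "A")
  ep <- eeg_segment(rec)
  feats <- band_power_features(ep, transform = "raw")
  bands <- eeg_bands()
  bins <- band_bin_index((0:128) * 0.5, bands)
  total_from_bands <- sum(as.matrix(feats[, -1]) *
                            rep(lengths(bins), each = nrow(feats)))
  arr <- array(unlist(ep$data), c(32, 1, nrow(ep)))
  psd <- psd_matrix(arr, 128)
  freq <- (0:(dim(psd)[1] - 1)) * 0.5
  total_direct <- sum(psd[freq >= 0.5 & freq <= 50, , ])
  expect_lt(abs(total_from_bands - total_direct) / total_direct, 1e-6)
})

test_that("scaling the signal scales raw power by s^2 and log power by 2 log10 s", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(128 * 2 * 2), ncol = 2), 128,
                       c("A", "B"))
  ep1 <- eeg_segment(rec)
  ep2 <- eeg_segment(rec_replace(rec, rec_matrix(rec) * 3))
  raw1 <- as.matrix(band_power_features(ep1, transform = "raw")[, -1])
  raw2 <- as.matrix(band_power_features(ep2, transform = "raw")[, -1])
  expect_equal(raw2, raw1 * 9, tolerance = 1e-12)
  log1 <- as.matrix(band_power_features(ep1)[, -1])
  log2 <- as.matrix(band_power_features(ep2)[, -1])
  # the +1e-12 offset makes the shift approximate at tiny powers
  expect_equal(log2, log1 + 2 * log10(3), tolerance = 1e-6)
})

test_that("planted synthetic effects surface at the planted cell", {
  hits <- sapply(1:10, function(s) {
    cfg <- planted_config(multiplier = 3, channel = "T8", band = "high_beta",
                          session_length = 20, seed = s)
    fn <- band_power_features(eeg_segment(simulate_session(cfg, "neutral")))
    fh <- band_power_features(eeg_segment(simulate_session(cfg, "happiness")))
    d <- (colMeans(fh[, -1]) - colMeans(fn[, -1])) /
      sqrt((apply(fh[, -1], 2, var) + apply(fn[, -1], 2, var)) / 2)
    names(which.max(d))
  })
  expect_true(all(hits == "T8_high_beta"))
})

test_that("an empty band is rejected", {
  rec <- eeg_recording(matrix(rnorm(128), ncol = 1), 128, "A")
  skinny <- tibble::tibble(band = "none", low = 10.1, high = 10.2)
  expect_error(band_power_features(eeg_segment(rec), bands = skinny),
               "no grid frequency")
})
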
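make_series <- function(values, subject = "S01", index = "happiness",
                        clip = "C1") {
  tibble::tibble(subject_id = subject, index_name = index, clip_id = clip,
                 window_start_s = (seq_along(values) - 1) * 0.25,
                 value = values)
}

test_that("index is the affine map 2p - 1 of the posterior", {
  dat <- gaussian_features(50, 2, shift = c(f1 = 3), seed = 1)
  fit <- flda(dat)
  series <- score_clip(dat, fit, "S01", "happiness", "C1")
  expect_equal(series$value, 2 * predict(fit, dat) - 1)
  expect_true(all(series$value >= -1 & series$value <= 1))
  # monotone link: index strictly increasing in posterior
  p <- predict(fit, dat)
  ord <- order(p)
  expect_true(all(diff(series$value[ord]) >= 0))
})

test_that("posterior endpoints map to index endpoints and 0.5 to zero", {
  fit <- structure(list(
    w = c(f1 = 1), features = "f1",
    projected = tibble::tibble(class = 0:1, mean = c(-1, 1), var = c(1, 1),
                               n = c(10L, 10L)),
    pooled_var = 1, ridge = 0, variance = "class"), class = "flda")
  at_mid <- score_clip(tibble::tibble(f1 = 0), fit)
  expect_equal(at_mid$value, 0)
  expect_equal(score_clip(tibble::tibble(f1 = 50), fit)$value, 1,
               tolerance = 1e-9)
  expect_equal(score_clip(tibble::tibble(f1 = -50), fit)$value, -1,
               tolerance = 1e-9)
})

test_that("clip summaries rank by group mean with label-order ties", {
  series <- dplyr::bind_rows(
    make_series(rep(0.5, 4), clip = "C1"),
    make_series(rep(0.5, 4), clip = "C2"),
    make_series(rep(0.5, 4), clip = "C3"))
  sm <- summarize_clips(series)
  expect_equal(sm$rank, 1:3)
  expect_equal(sm$clip_id, c("C1", "C2", "C3"))
  # single subject, constant value: mean v, sd NA -> 0 subjects aside
  one <- summarize_clips(make_series(rep(0.3, 10)))
  expect_equal(one$mean, 0.3)
  expect_true(is.na(one$sd))  # single subject has no between-subject SD
  # ranks are a permutation and the largest mean ranks first
  series2 <- dplyr::bind_rows(
    make_series(rep(0.9, 4), clip = "C2"),
    make_series(rep(-0.2, 4), clip = "C1"))
  sm2 <- summarize_clips(series2)
  expect_equal(sm2$clip_id[sm2$rank == 1], "C2")
  expect_error(summarize_clips(series2[0, ]), "empty")
})

test_that("group averaging is the pointwise mean, truncated to the shortest", {
  s1 <- make_series(c(0.2, 0.4, 0.6), subject = "A")
  s2 <- make_series(c(-0.2, -0.4, -0.6, 0.9), subject = "B")
  avg <- group_average_series(dplyr::bind_rows(s1, s2))
  expect_equal(nrow(avg), 3)
  expect_equal(avg$value, c(0, 0, 0))
  # one subject -> identity
  solo <- group_average_series(s1)
  expect_equal(solo$value, s1$value)
  # brute-force mean oracle on random series
  set.seed(2)
  many <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_series(runif(8, -1, 1), subject = paste0("S", i))
  }))
  avg5 <- group_average_series(many)
  direct <- colMeans(matrix(many$value, nrow = 5, byrow = TRUE))
  expect_equal(avg5$value, direct, tolerance = 1e-12)
  expect_error(group_average_series(s1[0, ]), "no subjects")
})

test_that("peak detection merges adjacent windows and keeps isolated ones", {
  v <- rep(0, 20)
  expect_equal(nrow(detect_peaks(make_series(v))), 0)
  # four isolated supra-threshold quarter-second windows
  v[c(3, 8, 13, 18)] <- 0.8
  pk <- detect_peaks(make_series(v))
  expect_equal(nrow(pk), 4)
  expect_equal(pk$end_s - pk$start_s, rep(0.25, 4))
  expect_equal(pk$start_s, c(2, 7, 12, 17) * 0.25)
  # adjacent windows merge
  v2 <- rep(0, 10); v2[4:5] <- 0.7
  pk2 <- detect_peaks(make_series(v2))
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$end_s - pk2$start_s, 0.5)
  expect_equal(pk2$peak, 0.7)
  # values exactly at the threshold do not qualify
  v3 <- rep(0.5, 5)
  expect_equal(nrow(detect_peaks(make_series(v3))), 0)
  expect_error(detect_peaks(make_series(v), threshold = 1.5), "threshold")
})

test_that("a step-trajectory clip scores higher in its second half", {
  wins <- sapply(1:10, function(s) {
    eff <- tibble::tibble(condition = "happiness", channel = "FC5",
                          band = "gamma", multiplier = 3)
    cfg <- synth_config(effects = eff, session_length = 30,
                        seed = 500 + s)
    neu <- band_power_features(eeg_segment(simulate_session(cfg, "neutral")))
    hap <- band_power_features(eeg_segment(simulate_session(cfg, "happiness")))
    lab <- label_features(neu, hap)
    fit <- flda(lab, features = c("FC5_gamma"))
    sim <- simulate_commercial(cfg, trajectory_step(at = 15), "C1")
    ft <- band_power_features(eeg_segment(sim$recording))
    sr <- score_clip(ft, fit)
    mean(sr$value[61:120]) > mean(sr$value[1:60])
  })
  expect_gte(sum(wins), 9)
})

test_that("plot functions return ggplot objects", {
  avg <- make_series(c(rep(0, 5), 0.8, rep(0, 4)))
  pk <- detect_peaks(avg)
  expect_s3_class(plot_index_series(avg, pk), "ggplot")
  sm <- summarize_clips(dplyr::bind_rows(
    make_series(rep(0.2, 4), clip = "C1"),
    make_series(rep(0.1, 4), clip = "C2")))
  expect_s3_class(plot_clip_summary(sm), "ggplot")
})
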
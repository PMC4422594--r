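# Shared fixtures: small synthetic problems built in code.

# Gaussian feature tibble with named columns and binary labels;
# `shift` moves the listed columns by that many SDs in class 1.
gaussian_features <- function(n_per_class, n_features, shift = numeric(0),
                              seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * n_features), 2 * n_per_class)
  colnames(X) <- paste0("f", seq_len(n_features))
  y <- rep(0:1, each = n_per_class)
  for (nm in names(shift)) {
    X[y == 1, nm] <- X[y == 1, nm] + shift[[nm]]
  }
  out <- tibble::as_tibble(X)
  out$window_start_s <- (seq_len(nrow(out)) - 1) * 0.25
  out$label <- y
  out
}

# single planted effect config used across generator tests
planted_config <- function(multiplier = 3, channel = "O1", band = "alpha",
                           session_length = 60, seed = 1, ...) {
  synth_config(
    effects = tibble::tibble(condition = "happiness", channel = channel,
                             band = band, multiplier = multiplier),
    session_length = session_length, seed = seed, ...)
}

# direct two-sided periodogram band integral (oracle, independent of the
# package's Hann/zero-padding feature path)
oracle_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)
  sum(p[f >= lo & f < hi]) / n
}

# pure sinusoid recording
tone_recording <- function(freq, rate = 128, seconds = 2, channels = 2,
                           amp = 1) {
  t <- (seq_len(rate * seconds) - 1) / rate
  x <- matrix(rep(amp * sin(2 * pi * freq * t), channels), ncol = channels)
  eeg_recording(x, rate, paste0("CH", seq_len(channels)))
}
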
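#' Configuration for synthetic EEG sessions
#'
#' Describes a reproducible synthetic study: background 1/f^alpha coloured
#' noise per channel, plus condition-specific planted effects, each a
#' band-limited Gaussian oscillation added to one (channel, band) cell with
#' amplitude calibrated so that the expected band power equals the neutral
#' band power times `multiplier`.
#'
#' @param montage Channel labels (default the 14-channel EPOC montage).
#' @param rate Sampling rate in Hz.
#' @param session_length Session duration in seconds.
#' @param effects Data frame with columns `condition`, `channel`, `band`,
#'   `multiplier` (all multipliers >= 1). Conditions other than `"neutral"`
#'   take their planted effects from here; neutral sessions are pure
#'   background noise.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param noise_sd Total background standard deviation per channel
#'   (microvolts).
#' @param shared_source Fraction in \[0, 1) of background variance drawn
#'   from a single source common to all channels (0 = independent
#'   channels).
#' @param seed Integer seed; identical (config, condition) pairs
#'   regenerate bit-identical sessions.
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(session_length = 4, seed = 1)
#' rec <- simulate_session(cfg, "neutral")
#' dim(rec)
synth_config <- function(montage = epoc_montage(), rate = 128,
                         session_length = 60,
                         effects = NULL,
                         noise_exponent = 1, noise_sd = 10,
                         shared_source = 0, seed = 1L) {
  if (is.null(effects)) {
    effects <- tibble::tibble(condition = character(), channel = character(),
                              band = character(), multiplier = numeric())
  }
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("condition", "channel", "band", "multiplier") %in%
                  names(effects)))
  if (any(effects$multiplier < 1)) {
    rlang::abort("planted-effect multipliers must be >= 1")
  }
  bad_ch <- setdiff(effects$channel, montage)
  if (length(bad_ch)) {
    rlang::abort(paste0("unknown channel in effects: ",
                        paste(bad_ch, collapse = ", ")))
  }
  bad_band <- setdiff(effects$band, eeg_bands()$band)
  if (length(bad_band)) {
    rlang::abort(paste0("unknown band in effects: ",
                        paste(bad_band, collapse = ", ")))
  }
  stopifnot(rate > 0, session_length > 0, noise_sd > 0,
            shared_source >= 0, shared_source < 1)
  structure(list(montage = montage, rate = rate,
                 session_length = session_length, effects = effects,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 shared_source = shared_source, seed = as.integer(seed)),
            class = "synth_config")
}

# spectral amplitude profile |H(f_k)| of the 1/f^alpha background on the
# full (two-sided) DFT grid; floor at 0.5 Hz keeps the variance finite
noise_shape <- function(n, rate, alpha) {
  f <- c(0, seq_len(n - 1)) / n * rate
  f <- pmin(f, rate - f)            # two-sided |frequency|
  h <- pmax(f, 0.5)^(-alpha / 2)
  h[1] <- 0                         # no DC
  h
}

# indicator shape of a band-limited component on the two-sided grid
band_shape <- function(n, rate, low, high) {
  f <- c(0, seq_len(n - 1)) / n * rate
  f <- pmin(f, rate - f)
  as.numeric(f >= low & f <= high)
}

# colour white noise by a two-sided amplitude profile h; output variance
# (expected) is sum(h^2)/n for unit-variance input
shape_noise <- function(w, h) {
  n <- length(w)
  Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
}

condition_labels <- function() {
  c("neutral", "happiness", "surprise", "attention", "commercial")
}

# deterministic per-(seed, condition, stream) RNG scope
with_synth_seed <- function(seed, label, code) {
  offset <- sum(utf8ToInt(label)) %% 104729L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 7919L + offset) %% .Machine$integer.max)
  force(code)
}

# core sampler: background noise plus planted band effects with a
# per-sample intensity envelope g(t) in [0, 1]
synth_samples <- function(config, effects, intensity, rng_label) {
  n <- round(config$session_length * config$rate)
  n_ch <- length(config$montage)
  h_bg <- noise_shape(n, config$rate, config$noise_exponent)
  bg_var <- sum(h_bg^2) / n                       # unit-input variance
  scale_bg <- config$noise_sd / sqrt(bg_var)
  with_synth_seed(config$seed, rng_label, {
    shared <- if (config$shared_source > 0)
      shape_noise(stats::rnorm(n), h_bg) * scale_bg else NULL
    x <- matrix(0, n, n_ch)
    for (j in seq_len(n_ch)) {
      own <- shape_noise(stats::rnorm(n), h_bg) * scale_bg
      x[, j] <- if (is.null(shared)) own else
        sqrt(1 - config$shared_source) * own + sqrt(config$shared_source) * shared
    }
    if (nrow(effects) > 0) {
      bands <- eeg_bands()
      for (i in seq_len(nrow(effects))) {
        ch <- match(effects$channel[i], config$montage)
        b <- bands[bands$band == effects$band[i], ]
        h_band <- band_shape(n, config$rate, b$low, b$high)
        # neutral band power of the background in this band
        p_band <- config$noise_sd^2 * sum(h_bg^2 * (h_band > 0)) / sum(h_bg^2)
        u <- shape_noise(stats::rnorm(n), h_band)
        u <- u / sqrt(sum(h_band^2) / n)          # unit variance carrier
        amp <- sqrt(pmax(intensity, 0) * (effects$multiplier[i] - 1) * p_band)
        x[, ch] <- x[, ch] + amp * u
      }
    }
    x
  })
}

#' Generate one synthetic calibration session
#'
#' Produces a stationary session of coloured-noise EEG. For non-neutral
#' conditions, the planted (channel, band) cells configured for that
#' condition carry an additive band-limited oscillation whose expected
#' band power is the neutral level times the configured multiplier; all
#' other cells are statistically identical to neutral.
#'
#' @param config A [synth_config()].
#' @param condition One of `"neutral"`, `"happiness"`, `"surprise"`,
#'   `"attention"`.
#' @return An [eeg_recording()] tibble.
#' @export
simulate_session <- function(config, condition) {
  stopifnot(inherits(config, "synth_config"))
  if (!condition %in% condition_labels()) {
    rlang::abort(paste0("unknown condition: ", condition))
  }
  eff <- dplyr::filter(config$effects, .data$condition == !!condition)
  x <- synth_samples(config, eff, intensity = 1, rng_label = condition)
  eeg_recording(x, config$rate, config$montage, session = condition)
}

#' Generate a synthetic commercial-viewing session with ground truth
#'
#' The planted effects of `condition` are modulated in time by a state
#' trajectory g(t) in \[0, 1\]: at intensity 0 the session is neutral, at
#' intensity 1 the effect is at full configured multiplier, and expected
#' band power interpolates linearly in between.
#'
#' @param config A [synth_config()].
#' @param trajectory Either a function of time (seconds) returning
#'   intensities in \[0, 1\], or a data frame with columns `time_s`,
#'   `intensity` interpreted as piecewise-linear breakpoints. Must be
#'   defined over the whole session.
#' @param clip_id Label for the clip (carried as the session attribute).
#' @param condition Which condition's planted effects the trajectory
#'   modulates (default `"happiness"`).
#' @return A list with elements `recording` (an [eeg_recording()]) and
#'   `truth`, a tibble (`window_start_s`, `intensity`) with one row per
#'   0.25-s window.
#' @export
simulate_commercial <- function(config, trajectory, clip_id = "C1",
                                condition = "happiness") {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$session_length * config$rate)
  t_samp <- (seq_len(n) - 1) / config$rate
  g <- eval_trajectory(trajectory, t_samp, config$session_length)
  eff <- dplyr::filter(config$effects, .data$condition == !!condition)
  x <- synth_samples(config, eff, intensity = g,
                     rng_label = paste0("commercial:", clip_id))
  rec <- eeg_recording(x, config$rate, config$montage, session = clip_id)
  win <- 0.25
  n_win <- floor(config$session_length / win)
  starts <- (seq_len(n_win) - 1) * win
  truth <- tibble::tibble(
    window_start_s = starts,
    intensity = eval_trajectory(trajectory, starts + win / 2,
                                config$session_length))
  list(recording = rec, truth = truth)
}

# evaluate a trajectory (function or breakpoint frame) at times t
eval_trajectory <- function(trajectory, t, session_length) {
  if (is.function(trajectory)) {
    g <- trajectory(t)
  } else if (is.data.frame(trajectory)) {
    stopifnot(all(c("time_s", "intensity") %in% names(trajectory)))
    g <- stats::approx(trajectory$time_s, trajectory$intensity,
                       xout = t, rule = 1)$y
  } else {
    rlang::abort("trajectory must be a function or a breakpoint data frame")
  }
  if (anyNA(g) || length(g) != length(t)) {
    rlang::abort("trajectory undefined over part of the session")
  }
  if (any(g < -1e-9 | g > 1 + 1e-9)) {
    rlang::abort("trajectory intensities must lie in [0, 1]")
  }
  pmin(pmax(g, 0), 1)
}

#' Piecewise-linear trajectory helpers
#'
#' `trajectory_constant()` holds a fixed intensity; `trajectory_step()`
#' switches from `low` to `high` at `at` seconds; `trajectory_triangle()`
#' rises linearly from 0 to 1 at `peak` and back to 0 at `end`.
#'
#' @param value,low,high,at,peak,end Scalars in seconds / intensity units.
#' @return A function of time suitable for [simulate_commercial()].
#' @name trajectories
#' @export
trajectory_constant <- function(value = 0) {
  force(value)
  function(t) rep(value, length(t))
}

#' @rdname trajectories
#' @export
trajectory_step <- function(at, low = 0, high = 1) {
  force(at); force(low); force(high)
  function(t) ifelse(t < at, low, high)
}

#' @rdname trajectories
#' @export
trajectory_triangle <- function(peak, end) {
  force(peak); force(end)
  function(t) {
    up <- pmin(pmax(t / peak, 0), 1)
    down <- pmin(pmax((end - t) / (end - peak), 0), 1)
    pmin(up, down)
  }
}
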
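#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a Butterworth band-pass applied
#' forward-backward (zero phase), realised as a cascade of a 2nd-order
#' high-pass at `low` and a 2nd-order low-pass at `high`. At 128 Hz
#' sampling the conventional 0.5-100 Hz analysis band exceeds Nyquist
#' (64 Hz); the upper edge is clamped to `0.45 * rate` with a warning.
#'
#' @param rec An EEG recording tibble (`time_s` plus channel columns).
#' @param low,high Band edges in Hz (defaults 0.5 and 100).
#' @return A recording tibble of the same shape.
#' @export
#' @examples
#' cfg <- synth_config(session_length = 2, seed = 1)
#' rec <- simulate_session(cfg, "neutral")
#' filtered <- eeg_bandpass(rec)
eeg_bandpass <- function(rec, low = 0.5, high = 100) {
  x <- rec_matrix(rec)
  rate <- rec_rate(rec)
  if (high <= low) rlang::abort("high edge must exceed low edge")
  if (!all(is.finite(x))) rlang::abort("recording contains non-finite samples")
  hi_max <- 0.45 * rate
  if (high > hi_max) {
    rlang::warn(sprintf(
      "upper edge %g Hz exceeds 0.45 x rate; clamped to %g Hz", high, hi_max))
    high <- hi_max
  }
  if (low <= 0 || high >= rate / 2) {
    rlang::abort("band edges must satisfy 0 < low < high < rate/2")
  }
  hp <- signal::butter(2, low / (rate / 2), type = "high")
  lp <- signal::butter(2, high / (rate / 2), type = "low")
  y <- apply(x, 2, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  })
  rec_replace(rec, y)
}

#' Common average reference
#'
#' Re-references each channel by subtracting the instantaneous mean across
#' all channels, so the cross-channel mean is exactly zero at every sample.
#'
#' @param rec An EEG recording tibble with at least two channels.
#' @return A recording tibble of the same shape.
#' @export
eeg_car <- function(rec) {
  x <- rec_matrix(rec)
  if (ncol(x) < 2) rlang::abort("common average reference needs >= 2 channels")
  rec_replace(rec, x - rowMeans(x))
}

#' Segment a recording into contiguous non-overlapping windows
#'
#' Splits the recording into quarter-second (by default) windows; a
#' trailing partial window is dropped.
#'
#' @param rec An EEG recording tibble.
#' @param window_s Window length in seconds (default 0.25).
#' @return A tibble of class `eeg_epochs` with columns `window` (1-based),
#'   `start_s`, and `data` (list of samples x channels matrices); sampling
#'   rate, montage and window length travel as attributes.
#' @export
eeg_segment <- function(rec, window_s = 0.25) {
  x <- rec_matrix(rec)
  rate <- rec_rate(rec)
  spw <- round(rate * window_s)
  if (nrow(x) < spw) rlang::abort("recording shorter than one window")
  n_win <- floor(nrow(x) / spw)
  idx <- seq_len(n_win * spw)
  mats <- lapply(seq_len(n_win), function(w) {
    x[((w - 1) * spw + 1):(w * spw), , drop = FALSE]
  })
  out <- tibble::tibble(
    window = seq_len(n_win),
    start_s = (seq_len(n_win) - 1) * window_s,
    data = mats
  )
  attr(out, "rate") <- rate
  attr(out, "montage") <- rec_montage(rec)
  attr(out, "window_s") <- window_s
  attr(out, "subject_id") <- attr(rec, "subject_id")
  attr(out, "session") <- attr(rec, "session")
  class(out) <- c("eeg_epochs", class(tibble::tibble()))
  out
}

#' Standard preprocessing chain
#'
#' Band-pass filter, common average reference, then segmentation — the
#' canonical order for quarter-second band-power analysis. Filtering and
#' re-referencing are both linear and time-invariant, so their order does
#' not affect the result.
#'
#' @inheritParams eeg_bandpass
#' @inheritParams eeg_segment
#' @return An `eeg_epochs` tibble.
#' @export
eeg_preprocess <- function(rec, low = 0.5, high = 100, window_s = 0.25) {
  rec |> eeg_bandpass(low, high) |> eeg_car() |> eeg_segment(window_s)
}
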
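# Hann-tapered periodogram of one window on a fixed frequency grid.
# A 0.25-s window at 128 Hz holds 32 samples (native 4 Hz resolution);
# zero-padding the tapered segment to rate/grid points puts the estimate
# on the conventional 0.5 Hz grid.

#' Power spectral density of a single window
#'
#' Hann-tapered, zero-padded periodogram of each channel of one window,
#' evaluated on a regular frequency grid from 0 Hz to Nyquist.
#'
#' @param window Numeric matrix, samples x channels (a single epoch).
#' @param rate Sampling rate in Hz.
#' @param grid Frequency bin spacing in Hz (default 0.5).
#' @return A tibble with columns `freq` and one PSD column per channel
#'   (power per Hz, non-negative).
#' @export
window_psd <- function(window, rate, grid = 0.5) {
  window <- as.matrix(window)
  if (nrow(window) < 2) rlang::abort("window must hold at least 2 samples")
  if (grid <= 0 || grid > rate / 2) {
    rlang::abort("grid spacing must lie in (0, rate/2]")
  }
  psd <- psd_matrix(array(window, c(nrow(window), ncol(window), 1)),
                    rate, grid)
  freq <- (seq_len(dim(psd)[1]) - 1) * grid
  out <- tibble::as_tibble(matrix(psd, nrow = dim(psd)[1]),
                           .name_repair = "minimal")
  names(out) <- colnames(window) %||% paste0("ch", seq_len(ncol(window)))
  tibble::add_column(out, freq = freq, .before = 1)
}

# epochs array (samples x channels x windows) -> PSD array
# (bins x channels x windows); one-sided, Hann taper, density scaling
psd_matrix <- function(arr, rate, grid = 0.5) {
  spw <- dim(arr)[1]
  nfft <- max(round(rate / grid), spw)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(spw) - 1) / (spw - 1))  # Hann
  scale <- 1 / (rate * sum(taper^2))
  n_bins <- floor(nfft / 2) + 1
  flat <- matrix(arr, nrow = spw)                  # channels*windows columns
  padded <- matrix(0, nfft, ncol(flat))
  padded[seq_len(spw), ] <- flat * taper
  spec <- stats::mvfft(padded)[seq_len(n_bins), , drop = FALSE]
  p <- (Mod(spec)^2) * scale
  p[-c(1, n_bins), ] <- 2 * p[-c(1, n_bins), ]     # one-sided doubling
  array(p, c(n_bins, dim(arr)[2], dim(arr)[3]))
}

# membership of grid bins in each band: [low, high) except the last band,
# closed at its upper edge
band_bin_index <- function(freq, bands) {
  lapply(seq_len(nrow(bands)), function(i) {
    closed <- i == nrow(bands)
    if (closed) which(freq >= bands$low[i] & freq <= bands$high[i])
    else which(freq >= bands$low[i] & freq < bands$high[i])
  })
}

#' Band-power features per window
#'
#' For each window and channel, averages the PSD bins whose frequency
#' falls in each band, giving one feature per (channel, band) cell —
#' 84 features for the 14-channel montage and six default bands. Columns
#' are ordered montage-major (all bands of channel 1, then channel 2, ...)
#' and named `CHANNEL_band`, e.g. `O1_alpha`.
#'
#' @param epochs An `eeg_epochs` tibble from [eeg_segment()].
#' @param bands Band definition tibble (default [eeg_bands()]).
#' @param transform `"log"` (default) stores `log10(power + 1e-12)`;
#'   `"raw"` stores the mean PSD itself.
#' @param grid Frequency bin spacing in Hz.
#' @return A tibble with `window_start_s` followed by one numeric column
#'   per feature.
#' @export
#' @examples
#' cfg <- synth_config(session_length = 2, seed = 1)
#' feats <- simulate_session(cfg, "neutral") |>
#'   eeg_segment() |>
#'   band_power_features()
#' dim(feats)  # 8 windows x (1 + 84)
band_power_features <- function(epochs, bands = eeg_bands(),
                                transform = c("log", "raw"), grid = 0.5) {
  transform <- match.arg(transform)
  stopifnot(inherits(epochs, "eeg_epochs"))
  rate <- attr(epochs, "rate")
  montage <- attr(epochs, "montage")
  if (any(bands$low < 0) || any(bands$high > rate / 2)) {
    rlang::abort("band edges must lie within [0, rate/2]")
  }
  spw <- nrow(epochs$data[[1]])
  arr <- array(unlist(epochs$data), c(spw, length(montage), nrow(epochs)))
  psd <- psd_matrix(arr, rate, grid)
  freq <- (seq_len(dim(psd)[1]) - 1) * grid
  bins <- band_bin_index(freq, bands)
  empty <- lengths(bins) == 0
  if (any(empty)) {
    rlang::abort(paste0("no grid frequency falls inside band: ",
                        paste(bands$band[empty], collapse = ", ")))
  }
  n_win <- nrow(epochs)
  vals <- matrix(NA_real_, n_win, length(montage) * nrow(bands))
  k <- 0
  for (ch in seq_along(montage)) {
    for (b in seq_len(nrow(bands))) {
      k <- k + 1
      sub <- psd[bins[[b]], ch, , drop = FALSE]
      vals[, k] <- colMeans(matrix(sub, nrow = length(bins[[b]])))
    }
  }
  if (transform == "log") vals <- log10(vals + 1e-12)
  colnames(vals) <- feature_names(montage, bands$band)
  out <- tibble::as_tibble(vals)
  out <- tibble::add_column(out, window_start_s = epochs$start_s, .before = 1)
  attr(out, "transform") <- transform
  attr(out, "subject_id") <- attr(epochs, "subject_id")
  attr(out, "session") <- attr(epochs, "session")
  out
}

#' Feature column names for a montage and band set
#'
#' @param montage Channel labels.
#' @param bands Band names.
#' @return Character vector `CHANNEL_band`, montage-major.
#' @export
feature_names <- function(montage = epoc_montage(),
                          bands = eeg_bands()$band) {
  as.vector(t(outer(montage, bands, paste, sep = "_")))
}

# numeric feature matrix view of a feature tibble
feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features),
                               c("window_start_s", "label", "session")),
                     drop = FALSE])
}
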
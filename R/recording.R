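#' Standard 14-channel Emotiv EPOC montage
#'
#' Channel labels of the 14-electrode wireless headset montage, in the
#' International 10/20 system, in recording order.
#'
#' @return Character vector of 14 channel labels.
#' @export
#' @examples
#' epoc_montage()
epoc_montage <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' Default EEG frequency band definitions
#'
#' The six canonical bands used for band-power feature extraction:
#' delta \[0.5, 4), theta \[4, 8), alpha \[8, 12), low beta \[12, 20),
#' high beta \[20, 30) and gamma \[30, 50\] Hz. Band membership of a
#' spectral bin is half-open on the right except gamma, which is closed
#' at 50 Hz, so the six bands partition \[0.5, 50\] without double
#' counting shared edges.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "low_beta", "high_beta", "gamma"),
    low  = c(0.5, 4, 8, 12, 20, 30),
    high = c(4, 8, 12, 20, 30, 50)
  )
}

#' Construct an EEG recording tibble
#'
#' A recording is a tibble with a `time_s` column followed by one numeric
#' column per channel (microvolts), sampled on a regular grid. Metadata
#' (sampling rate, subject, session label) travel as attributes but every
#' function re-derives the rate from the timestamps, so plain tibbles read
#' from disk work identically.
#'
#' @param data Numeric matrix, samples x channels.
#' @param rate Sampling rate in Hz.
#' @param montage Character vector of channel labels (unique, one per
#'   column of `data`).
#' @param subject_id,session Optional labels carried as attributes.
#' @return A tibble of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, montage = epoc_montage(),
                          subject_id = NA_character_, session = NA_character_) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), rate > 0)
  if (length(montage) != ncol(data)) {
    rlang::abort(sprintf("montage has %d labels but data has %d channels",
                         length(montage), ncol(data)))
  }
  if (anyDuplicated(montage)) rlang::abort("montage labels must be unique")
  colnames(data) <- montage
  out <- tibble::as_tibble(data)
  out <- tibble::add_column(out,
                            time_s = (seq_len(nrow(data)) - 1) / rate,
                            .before = 1)
  attr(out, "rate") <- rate
  attr(out, "subject_id") <- subject_id
  attr(out, "session") <- session
  class(out) <- c("eeg_recording", class(tibble::tibble()))
  out
}

# samples x channels matrix view of a recording tibble
rec_matrix <- function(rec) {
  as.matrix(rec[, setdiff(names(rec), "time_s"), drop = FALSE])
}

rec_montage <- function(rec) setdiff(names(rec), "time_s")

# sampling rate, from the attribute if present else from the time stamps
rec_rate <- function(rec) {
  r <- attr(rec, "rate")
  if (!is.null(r) && is.finite(r)) return(r)
  dt <- diff(rec$time_s)
  if (length(dt) == 0) rlang::abort("recording has fewer than 2 samples")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    rlang::abort("irregular timestamps: cannot infer a sampling rate")
  }
  1 / stats::median(dt)
}

# rebuild a recording tibble around a new sample matrix, keeping metadata
rec_replace <- function(rec, new_data) {
  eeg_recording(new_data, rec_rate(rec), rec_montage(rec),
                subject_id = attr(rec, "subject_id") %||% NA_character_,
                session = attr(rec, "session") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
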
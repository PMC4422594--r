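#' Score a clip into a normalized index time series
#'
#' Applies a trained discriminant to each quarter-second window of a
#' clip's feature matrix, converts the posterior probability p of the
#' target state to the index 2p - 1, the unique affine map of \[0, 1\]
#' posteriors onto the \[-1, 1\] index range (larger positive values mean
#' the state is expressed more strongly).
#'
#' @param features Feature tibble of the clip (must contain every feature
#'   the model was trained on).
#' @param model A fitted [flda()] object.
#' @param subject_id,index_name,clip_id Labels stored in the output.
#' @return An index-series tibble: `subject_id`, `index_name`, `clip_id`,
#'   `window_start_s`, `value` in \[-1, 1\].
#' @export
score_clip <- function(features, model, subject_id = NA_character_,
                       index_name = NA_character_, clip_id = NA_character_) {
  p <- predict(model, features)
  tibble::tibble(
    subject_id = subject_id,
    index_name = index_name,
    clip_id = clip_id,
    window_start_s = if ("window_start_s" %in% names(features))
      features$window_start_s else (seq_along(p) - 1) * 0.25,
    value = 2 * p - 1
  )
}

#' Summarize and rank clips by mean index
#'
#' Averages each subject's index over windows, then summarises across
#' subjects per (clip, index): group mean, SD and rank (1 = largest group
#' mean; ties broken by clip label order).
#'
#' @param series Index-series tibble (rows from [score_clip()], possibly
#'   many subjects/clips/indices bound together).
#' @return A tibble per (index_name, clip_id): `mean`, `sd`, `n_subjects`,
#'   `rank`.
#' @export
summarize_clips <- function(series) {
  if (nrow(series) == 0) rlang::abort("empty index series")
  series |>
    dplyr::group_by(.data$index_name, .data$clip_id, .data$subject_id) |>
    dplyr::summarise(subject_mean = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$index_name, .data$clip_id) |>
    dplyr::summarise(mean = mean(.data$subject_mean),
                     sd = stats::sd(.data$subject_mean),
                     n_subjects = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$index_name) |>
    dplyr::arrange(dplyr::desc(.data$mean), .data$clip_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Group-average index series for one clip
#'
#' Pointwise mean of per-subject index series on a common window grid;
#' subjects are truncated to the shortest series.
#'
#' @param series Index-series tibble for a single (clip, index) across
#'   subjects.
#' @return A tibble `window_start_s`, `value` (plus the clip/index
#'   labels), averaged across subjects.
#' @export
group_average_series <- function(series) {
  if (nrow(series) == 0) rlang::abort("no subjects to average")
  stopifnot(length(unique(series$clip_id)) == 1,
            length(unique(series$index_name)) == 1)
  n_min <- series |>
    dplyr::count(.data$subject_id) |>
    dplyr::pull(.data$n) |>
    min()
  series |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_head(n = n_min) |>
    dplyr::mutate(.win = dplyr::row_number()) |>
    dplyr::group_by(.data$.win) |>
    dplyr::summarise(index_name = .data$index_name[1],
                     clip_id = .data$clip_id[1],
                     window_start_s = .data$window_start_s[1],
                     value = mean(.data$value), .groups = "drop") |>
    dplyr::select(-".win")
}

#' Locate supra-threshold peak windows
#'
#' Finds maximal runs of consecutive windows whose index value exceeds
#' the threshold; adjacent supra-threshold windows merge into one peak,
#' and isolated single windows are valid quarter-second peaks.
#'
#' @param avg An averaged index-series tibble (`window_start_s`, `value`).
#' @param threshold Index threshold in (-1, 1); default 0.5.
#' @param window_s Window length in seconds used for the end time.
#' @return A tibble of peak windows: `start_s`, `end_s`, `peak`,
#'   `threshold` (empty if no window qualifies).
#' @export
detect_peaks <- function(avg, threshold = 0.5, window_s = 0.25) {
  if (threshold <= -1 || threshold >= 1) {
    rlang::abort("threshold must lie in (-1, 1)")
  }
  above <- avg$value > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  tibble::tibble(
    start_s = avg$window_start_s[starts[keep]],
    end_s = avg$window_start_s[ends[keep]] + window_s,
    peak = vapply(keep, function(i) {
      max(avg$value[starts[i]:ends[i]])
    }, numeric(1)),
    threshold = threshold
  )
}

#' Plot an index time series
#'
#' Line plot of the (group-average) index over elapsed time, with the
#' peak threshold and any detected peak windows shaded.
#'
#' @param avg Index-series tibble (`window_start_s`, `value`).
#' @param peaks Optional peak tibble from [detect_peaks()].
#' @param threshold Threshold line to draw (default 0.5).
#' @return A ggplot object.
#' @export
plot_index_series <- function(avg, peaks = NULL, threshold = 0.5) {
  p <- ggplot2::ggplot(avg, ggplot2::aes(.data$window_start_s, .data$value)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "elapsed time (s)", y = "index",
                  title = unique(avg$index_name)[1]) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -1, ymax = 1),
      inherit.aes = FALSE, alpha = 0.15, fill = "orange")
  }
  p
}

#' Plot clip summaries as a ranked bar chart
#'
#' @param summary A tibble from [summarize_clips()].
#' @return A ggplot object with one panel per index.
#' @export
plot_clip_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$clip_id, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~index_name) +
    ggplot2::labs(x = "clip", y = "group mean index") +
    ggplot2::theme_minimal()
}
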
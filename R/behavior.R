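#' Convert preference ranks to points
#'
#' Rank r of n clips becomes n + 1 - r points, so with four clips the
#' first, second, third and fourth ranks score 4, 3, 2 and 1 points.
#'
#' @param rank Integer rank(s), 1 = best.
#' @param n_clips Number of clips ranked (default 4).
#' @return Numeric points, same length as `rank`.
#' @export
#' @examples
#' rank_to_points(1:4)  # 4 3 2 1
rank_to_points <- function(rank, n_clips = 4) {
  if (any(rank < 1 | rank > n_clips | rank != round(rank))) {
    rlang::abort(sprintf("ranks must be integers in 1..%d", n_clips))
  }
  n_clips + 1 - rank
}

#' Score a behavioural record table
#'
#' Converts the rank columns of a behavioural table (one row per subject
#' per clip: `preference_rank`, `stm_rank`, `recall_rank`) to points and
#' keeps the Likert purchase-intention rating as-is.
#'
#' @param records Tibble with columns `subject_id`, `clip_id` and any of
#'   `preference_rank`, `stm_rank`, `recall_rank`, `purchase_intention`.
#' @return The input with `preference`, `stm`, `recall` point columns
#'   added.
#' @export
score_behavior <- function(records) {
  n_clips <- length(unique(records$clip_id))
  out <- records
  for (col in c("preference_rank", "stm_rank", "recall_rank")) {
    if (col %in% names(records)) {
      out[[sub("_rank$", "", col)]] <- rank_to_points(records[[col]], n_clips)
    }
  }
  if ("purchase_intention" %in% names(records) &&
      any(records$purchase_intention < 1 | records$purchase_intention > 7)) {
    rlang::abort("purchase_intention must lie on the 1-7 Likert scale")
  }
  tibble::as_tibble(out)
}

#' Compare clips on a per-subject score
#'
#' Omnibus one-way ANOVA of the score across clips followed by all
#' pairwise comparisons with Holm adjustment, flagged at alpha = 0.05 and
#' 0.01. The default treats points as interval-scaled and uses paired
#' t-tests (within-subject design); `method = "rank"` substitutes the
#' Friedman test and paired Wilcoxon signed-rank tests.
#'
#' @param data Tibble with columns `subject_id`, `clip_id` and the score
#'   column named by `value`.
#' @param value Name of the score column (default `"value"`).
#' @param method `"parametric"` (ANOVA + paired t) or `"rank"`
#'   (Friedman + Wilcoxon).
#' @return A list of class `clip_comparison`: `omnibus` (one-row tibble
#'   with statistic, df, p), `pairwise` (tibble with raw and
#'   Holm-adjusted p-values and significance flags) and `method`.
#' @export
compare_groups <- function(data, value = "value",
                           method = c("parametric", "rank")) {
  method <- match.arg(method)
  clips <- sort(unique(data$clip_id))
  subjects <- unique(data$subject_id)
  if (length(clips) < 2 || length(subjects) < 2) {
    rlang::abort("need >= 2 clips and >= 2 subjects")
  }
  v <- data[[value]]
  clip <- factor(data$clip_id, levels = clips)

  if (method == "parametric") {
    fit <- stats::aov(v ~ clip)
    an <- summary(fit)[[1]]
    omnibus <- tibble::tibble(
      test = "one-way ANOVA",
      statistic = an[["F value"]][1],
      df1 = an[["Df"]][1], df2 = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1]
    )
  } else {
    wide <- tidyr::pivot_wider(
      data[, c("subject_id", "clip_id", value)],
      names_from = "clip_id", values_from = dplyr::all_of(value))
    m <- as.matrix(wide[, clips, drop = FALSE])
    fr <- stats::friedman.test(m)
    omnibus <- tibble::tibble(
      test = "Friedman",
      statistic = unname(fr$statistic),
      df1 = unname(fr$parameter), df2 = NA_real_,
      p_value = fr$p.value
    )
  }

  pairs <- utils::combn(clips, 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    a <- data[data$clip_id == pr[1], ]
    b <- data[data$clip_id == pr[2], ]
    a <- a[match(subjects, a$subject_id), ]
    b <- b[match(subjects, b$subject_id), ]
    diff <- a[[value]] - b[[value]]
    if (stats::sd(diff) == 0) {
      tt <- list(statistic = NA_real_,
                 p.value = if (all(diff == 0)) 1 else 0)
    } else if (method == "parametric") {
      tt <- stats::t.test(a[[value]], b[[value]], paired = TRUE)
    } else {
      tt <- suppressWarnings(
        stats::wilcox.test(a[[value]], b[[value]], paired = TRUE))
    }
    tibble::tibble(clip_a = pr[1], clip_b = pr[2],
                   statistic = unname(tt$statistic)[1],
                   p_raw = tt$p.value)
  })
  pw$p_adjusted <- stats::p.adjust(pw$p_raw, method = "holm")
  pw$sig_05 <- pw$p_adjusted < 0.05
  pw$sig_01 <- pw$p_adjusted < 0.01

  structure(list(omnibus = omnibus, pairwise = pw, method = method,
                 value = value),
            class = "clip_comparison")
}

#' @export
print.clip_comparison <- function(x, ...) {
  cat("Omnibus (", x$omnibus$test, "): statistic = ",
      signif(x$omnibus$statistic, 4), ", p = ",
      signif(x$omnibus$p_value, 4), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' Tidy pairwise comparisons
#'
#' @param x A `clip_comparison` object.
#' @param ... Unused.
#' @return The pairwise tibble.
#' @export
tidy.clip_comparison <- function(x, ...) x$pairwise

#' One-row omnibus summary
#'
#' @param x A `clip_comparison` object.
#' @param ... Unused.
#' @return The omnibus tibble with the method attached.
#' @export
glance.clip_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus, method = x$method)
}
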
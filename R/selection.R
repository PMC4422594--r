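#' Pool neutral and target-condition features with binary labels
#'
#' Stacks the feature rows of a neutral calibration session and one
#' target-condition session and attaches the class label used by the
#' selection and discriminant stages (0 = neutral, 1 = target).
#'
#' @param neutral,target Feature tibbles from [band_power_features()].
#' @return A labelled feature tibble with a `label` column.
#' @export
label_features <- function(neutral, target) {
  stopifnot(nrow(neutral) > 0, nrow(target) > 0)
  feats <- setdiff(names(neutral), c("window_start_s", "label"))
  stopifnot(identical(feats, setdiff(names(target),
                                     c("window_start_s", "label"))))
  dplyr::bind_rows(
    dplyr::mutate(neutral, label = 0L),
    dplyr::mutate(target, label = 1L)
  )
}

#' One-way ANOVA F statistic per feature
#'
#' Computes the one-way ANOVA F value of each feature column against the
#' class label. With two classes this equals the squared pooled-variance
#' two-sample t statistic. Features with zero within-group variance get
#' `Inf` with a warning.
#'
#' @param data A labelled feature tibble (see [label_features()]).
#' @return A tibble (`feature`, `f_value`) in feature-column order.
#' @export
anova_f <- function(data) {
  y <- data$label
  X <- feature_matrix(data)
  k <- length(unique(y))
  if (any(table(y) < 2)) rlang::abort("each class needs >= 2 windows")
  n <- nrow(X)
  grand <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (g in unique(y)) {
    Xg <- X[y == g, , drop = FALSE]
    mg <- colMeans(Xg)
    ssb <- ssb + nrow(Xg) * (mg - grand)^2
    ssw <- ssw + colSums(sweep(Xg, 2, mg)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  if (any(ssw == 0)) {
    rlang::warn("zero within-group variance for some feature(s); F set to Inf")
    f[ssw == 0] <- Inf
  }
  tibble::tibble(feature = colnames(X), f_value = unname(f))
}

#' Stratified cross-validation folds
#'
#' Deterministic stratified assignment of rows to folds: within each
#' class, rows are permuted by the seeded RNG and dealt round-robin.
#'
#' @param labels Binary label vector.
#' @param folds Number of folds.
#' @param seed Integer seed fixing the assignment.
#' @return Integer fold id per row.
#' @export
cv_folds <- function(labels, folds = 10, seed = 1L) {
  if (any(table(labels) < folds)) {
    rlang::abort("each class must hold at least `folds` windows")
  }
  fold_id <- integer(length(labels))
  with_synth_seed(as.integer(seed), "cv-folds", {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Cross-validated accuracy of a feature subset
#'
#' Tenfold (by default) stratified cross-validation of the Fisher
#' discriminant restricted to `features`: train on nine folds, classify
#' the held-out fold at the 0.5 posterior threshold, and pool
#' correct/total over all folds.
#'
#' @param data A labelled feature tibble.
#' @param features Character vector of feature columns to use.
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param fold_id Optional precomputed fold assignment (overrides
#'   `folds`/`seed`).
#' @return Accuracy fraction in \[0, 1\].
#' @export
cross_validate <- function(data, features, folds = 10, seed = 1L,
                           fold_id = NULL) {
  y <- data$label
  X <- feature_matrix(data)[, features, drop = FALSE]
  if (is.null(fold_id)) fold_id <- cv_folds(y, folds, seed)
  cv_accuracy_matrix(X, y, fold_id)
}

# pooled held-out accuracy over folds; X already restricted to the subset
cv_accuracy_matrix <- function(X, y, fold_id) {
  correct <- 0L
  for (k in sort(unique(fold_id))) {
    test <- fold_id == k
    core <- flda_core(X[!test, , drop = FALSE], y[!test])
    z <- drop(X[test, , drop = FALSE] %*% core$w)
    pred <- as.integer(flda_core_posterior(core, z) >= 0.5)
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}

#' ANOVA-seeded greedy forward feature selection
#'
#' Starts from the feature with the highest one-way ANOVA F value, then
#' repeatedly adds the candidate that maximises tenfold cross-validated
#' accuracy of the augmented set, stopping at the first step whose best
#' achievable accuracy is strictly lower than the current one. Plateau
#' steps (equal accuracy) continue the search, but features added during
#' a plateau are kept only if a later step strictly improves on it; the
#' returned set is truncated at the last strict improvement. Ties between
#' candidates are broken by higher F value, then lower feature index.
#'
#' @param data A labelled feature tibble (see [label_features()]).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed fixing the fold assignment (one assignment reused for
#'   every candidate evaluation).
#' @param max_features Hard iteration cap (default: all features).
#' @param subject_id,index_name Labels carried into the result.
#' @return An object of class `eeg_selection`: a list with `chosen`
#'   (tibble `rank`, `feature`, `f_value`, `cv_accuracy`), `f_values`,
#'   `final_cv_accuracy`, `trajectory`, `folds`, `seed` and the labels.
#' @export
select_features <- function(data, folds = 10, seed = 1L,
                            max_features = NULL,
                            subject_id = NA_character_,
                            index_name = NA_character_) {
  fvals <- anova_f(data)
  y <- data$label
  X <- feature_matrix(data)
  feats <- fvals$feature
  if (is.null(max_features)) max_features <- length(feats)
  fold_id <- cv_folds(y, folds, seed)

  # seed with the top-F feature (ties: first index)
  current <- which.max(fvals$f_value)
  trajectory <- cv_accuracy_matrix(X[, current, drop = FALSE], y, fold_id)

  repeat {
    if (length(current) >= max_features) break
    remaining <- setdiff(seq_along(feats), current)
    accs <- vapply(remaining, function(j) {
      cv_accuracy_matrix(X[, c(current, j), drop = FALSE], y, fold_id)
    }, numeric(1))
    best_acc <- max(accs)
    if (best_acc < utils::tail(trajectory, 1)) break
    tied <- remaining[accs == best_acc]
    pick <- tied[order(-fvals$f_value[tied], tied)][1]
    current <- c(current, pick)
    trajectory <- c(trajectory, best_acc)
  }

  # truncate trailing plateau: keep up to the last strict improvement
  improved <- c(TRUE, diff(trajectory) > 0)
  keep <- max(which(improved))
  current <- current[seq_len(keep)]
  trajectory_kept <- trajectory[seq_len(keep)]

  chosen <- tibble::tibble(
    rank = seq_along(current),
    feature = feats[current],
    f_value = fvals$f_value[current],
    cv_accuracy = trajectory_kept
  )
  structure(list(chosen = chosen, f_values = fvals,
                 final_cv_accuracy = utils::tail(trajectory_kept, 1),
                 trajectory = trajectory, folds = folds,
                 seed = as.integer(seed),
                 subject_id = subject_id, index_name = index_name),
            class = "eeg_selection")
}

#' @export
print.eeg_selection <- function(x, ...) {
  cat("Greedy forward selection (", x$folds, "-fold CV): ",
      nrow(x$chosen), " feature(s), accuracy ",
      round(x$final_cv_accuracy, 4), "\n", sep = "")
  print(x$chosen)
  invisible(x)
}

#' Tidy a selection result
#'
#' @param x An `eeg_selection` object.
#' @param ... Unused.
#' @return The chosen-feature tibble with subject and index labels.
#' @export
tidy.eeg_selection <- function(x, ...) {
  dplyr::mutate(x$chosen, subject_id = x$subject_id,
                index_name = x$index_name)
}

#' One-row summary of a selection result
#'
#' @param x An `eeg_selection` object.
#' @param ... Unused.
#' @return Tibble with set size and final cross-validated accuracy.
#' @export
glance.eeg_selection <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, index_name = x$index_name,
    n_features = nrow(x$chosen),
    cv_accuracy = x$final_cv_accuracy,
    folds = x$folds, seed = x$seed
  )
}
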
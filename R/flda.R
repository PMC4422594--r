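#' Fit a two-class Fisher linear discriminant
#'
#' Finds the projection vector w maximising the Fisher criterion
#' J(w) = (w' S_B w) / (w' S_W w), where S_B is the between-class scatter
#' of the two class means about the grand mean and S_W the within-class
#' scatter of points about their class means. For two classes the maximiser
#' is w proportional to (S_W + ridge I)^-1 (mu1 - mu0); w is returned unit
#' length with the sign fixed so the target class projects higher.
#' Posterior probabilities use one-dimensional Gaussian class-conditionals
#' on z = w'x with the projected per-class means and variances and equal
#' priors.
#'
#' @param data A data frame whose feature columns are numeric and which
#'   carries the class in `label` (0 = neutral/reference, 1 = target), or
#'   a numeric matrix (then supply `labels`).
#' @param labels Optional binary vector when `data` is a matrix.
#' @param features Optional character vector restricting which columns are
#'   used (default: all numeric columns except `window_start_s`, `label`).
#' @param ridge Ridge added to S_W before inversion; default
#'   `1e-6 * trace(S_W) / d`.
#' @param variance `"class"` (default) uses per-class projected variances
#'   in the posterior; `"pooled"` uses the pooled projected variance.
#' @return An object of class `flda` with elements `w`, `features`,
#'   `class_means`, `grand_mean`, `S_B`, `S_W`, `ridge`,
#'   `projected` (per-class mean/variance on the discriminant axis) and
#'   `variance`.
#' @export
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, 2), 50))
#' fit <- flda(X, labels = rep(0:1, each = 50))
#' round(fit$w, 2)
flda <- function(data, labels = NULL, features = NULL,
                 ridge = NULL, variance = c("class", "pooled")) {
  variance <- match.arg(variance)
  if (is.data.frame(data)) {
    y <- data$label
    X <- feature_matrix(data)
  } else {
    X <- as.matrix(data)
    y <- labels
  }
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  if (is.null(y) || length(y) != nrow(X)) {
    rlang::abort("labels must match the number of rows")
  }
  if (!all(y %in% 0:1)) rlang::abort("labels must be 0/1")
  if (ncol(X) == 0) rlang::abort("no features to fit on")
  core <- flda_core(X, y, ridge, variance)
  projected <- tibble::tibble(
    class = c(0L, 1L),
    mean = c(core$m0, core$m1),
    var = c(core$v0, core$v1),
    n = c(core$n0, core$n1)
  )
  structure(list(w = stats::setNames(core$w, colnames(X)),
                 features = colnames(X),
                 class_means = rbind(`0` = core$mu0, `1` = core$mu1),
                 grand_mean = core$grand, S_B = core$S_B, S_W = core$S_W,
                 ridge = core$ridge, projected = projected,
                 pooled_var = core$pooled, variance = variance),
            class = "flda")
}

# matrix-level fit shared by flda() and the cross-validation inner loop;
# single source of the discriminant math
flda_core <- function(X, y, ridge = NULL, variance = "class") {
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 < 2 || n1 < 2) rlang::abort("each class needs at least 2 points")
  X0 <- X[y == 0, , drop = FALSE]
  X1 <- X[y == 1, , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  grand <- colMeans(X)
  d0 <- mu0 - grand; d1 <- mu1 - grand
  S_B <- tcrossprod(d0) + tcrossprod(d1)
  C0 <- X0 - rep(mu0, each = n0)
  C1 <- X1 - rep(mu1, each = n1)
  S_W <- crossprod(C0) + crossprod(C1)
  d <- ncol(X)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(S_W)) / d
  w <- drop(solve(S_W + diag(ridge, d), mu1 - mu0))
  nw <- sqrt(sum(w^2))
  if (!is.finite(nw) || nw == 0) {
    # coincident class means: no preferred direction
    rlang::warn("class means coincide; using the first coordinate axis")
    w <- c(1, rep(0, d - 1))
  } else {
    w <- w / nw
    if (sum(w * (mu1 - mu0)) < 0) w <- -w
  }
  z <- drop(X %*% w)
  z0 <- z[y == 0]; z1 <- z[y == 1]
  v0 <- stats::var(z0); v1 <- stats::var(z1)
  pooled <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  if (variance == "pooled") v0 <- v1 <- pooled
  list(w = w, mu0 = mu0, mu1 = mu1, grand = grand, S_B = S_B, S_W = S_W,
       ridge = ridge, m0 = mean(z0), m1 = mean(z1), v0 = v0, v1 = v1,
       pooled = pooled, n0 = n0, n1 = n1)
}

# posterior of class 1 from projected values z under a fitted core
flda_core_posterior <- function(core, z) {
  v0 <- core$v0; v1 <- core$v1
  if (!is.finite(v0) || v0 <= 0) v0 <- core$pooled
  if (!is.finite(v1) || v1 <= 0) v1 <- core$pooled
  if (!is.finite(v0) || v0 <= 0 || !is.finite(v1) || v1 <= 0) {
    return(as.numeric(z >= (core$m0 + core$m1) / 2))
  }
  stats::plogis(.log_dnorm(z, core$m1, v1) - .log_dnorm(z, core$m0, v0))
}

#' Fisher criterion value of a direction
#'
#' Evaluates J(w) = (w' S_B w) / (w' S_W w) for an arbitrary direction
#' under a fitted model's scatter matrices.
#'
#' @param model A fitted [flda()] object.
#' @param w Direction vector (any nonzero scale).
#' @return Scalar criterion value.
#' @export
fisher_criterion <- function(model, w = model$w) {
  drop(crossprod(w, model$S_B %*% w) / crossprod(w, model$S_W %*% w))
}

# log-density of N(mean, var) at z, guarded against zero variance
.log_dnorm <- function(z, mean, var) {
  -0.5 * log(2 * pi * var) - (z - mean)^2 / (2 * var)
}

#' Posterior probability of the target class
#'
#' Bayes posterior of class 1 under the model's one-dimensional Gaussian
#' class-conditionals on the discriminant axis, with equal priors. Falls
#' back to the pooled projected variance if a class variance is zero, and
#' to a hard threshold at the projected midpoint if both are zero.
#'
#' @param object A fitted [flda()] object.
#' @param newdata A data frame containing the model's feature columns, or
#'   a numeric matrix/vector in the model's feature space.
#' @param ... Unused.
#' @return Numeric vector of posteriors in \[0, 1\], one per row.
#' @export
predict.flda <- function(object, newdata, ...) {
  X <- coerce_newdata(object, newdata)
  z <- drop(X %*% object$w)
  p <- object$projected
  flda_core_posterior(
    list(m0 = p$mean[1], m1 = p$mean[2], v0 = p$var[1], v1 = p$var[2],
         pooled = object$pooled_var), z)
}

coerce_newdata <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$features, names(newdata))
    if (length(missing)) {
      rlang::abort(paste0("missing feature column(s): ",
                          paste(missing, collapse = ", ")))
    }
    X <- as.matrix(newdata[, object$features, drop = FALSE])
  } else {
    X <- newdata
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    if (ncol(X) != length(object$features)) {
      rlang::abort("feature dimension mismatch")
    }
  }
  X
}

#' Hard classification at the 0.5 posterior threshold
#'
#' @inheritParams predict.flda
#' @param model A fitted [flda()] object.
#' @return Integer vector of 0/1 labels; ties at posterior 0.5 go to the
#'   target class.
#' @export
flda_classify <- function(model, newdata) {
  as.integer(predict(model, newdata) >= 0.5)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the projection vector of a fitted discriminant
#'
#' @param x A fitted [flda()] object.
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature`, `weight`, and the
#'   class means on that feature.
#' @export
tidy.flda <- function(x, ...) {
  tibble::tibble(
    feature = x$features,
    weight = unname(x$w),
    mean_neutral = unname(x$class_means["0", ]),
    mean_target = unname(x$class_means["1", ])
  )
}

#' One-row summary of a fitted discriminant
#'
#' @param x A fitted [flda()] object.
#' @param ... Unused.
#' @return A tibble with the dimension, criterion value J(w), projected
#'   class separation and ridge used.
#' @export
glance.flda <- function(x, ...) {
  p <- x$projected
  sep <- abs(p$mean[2] - p$mean[1]) /
    sqrt((p$var[1] + p$var[2]) / 2)
  tibble::tibble(
    n_features = length(x$features),
    n_obs = sum(p$n),
    criterion = fisher_criterion(x),
    projected_separation = sep,
    ridge = x$ridge
  )
}

#' @export
print.flda <- function(x, ...) {
  cat("Fisher linear discriminant:", length(x$features), "feature(s)\n")
  cat("  J(w) =", signif(fisher_criterion(x), 4), "\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
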
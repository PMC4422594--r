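test_that("one-dimensional fit returns the only direction, target high", {
  dat <- gaussian_features(20, 1, shift = c(f1 = 3), seed = 1)
  fit <- flda(dat)
  expect_equal(abs(unname(fit$w)), 1)
  expect_gt(sum(fit$w * (fit$class_means["1", ] - fit$class_means["0", ])), 0)
})

test_that("isotropic classes separated along one axis give an axis-aligned w", {
  set.seed(2)
  X <- rbind(matrix(rnorm(2000), 1000), matrix(rnorm(2000), 1000))
  X[1001:2000, 1] <- X[1001:2000, 1] + 10
  fit <- flda(X, labels = rep(0:1, each = 1000))
  expect_lt(abs(unname(fit$w[1])) - 1, 1e-6)
  expect_lt(abs(unname(fit$w[2])), 0.05)
})

test_that("fitted w maximises the Fisher criterion (grid-search oracle)", {
  # brute-force maximisation of J over unit-circle directions
  worst <- Inf
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    X <- rbind(matrix(rnorm(2 * n), n) %*% matrix(runif(4, -1, 1), 2),
               matrix(rnorm(2 * n), n) %*% matrix(runif(4, -1, 1), 2) +
                 rep(runif(2, -2, 2), each = n))
    y <- rep(0:1, each = n)
    fit <- flda(X, labels = y, ridge = 0)
    th <- seq(0, pi, length.out = 1e4)
    j_grid <- vapply(seq_along(th), function(i) {
      fisher_criterion(fit, c(cos(th[i]), sin(th[i])))
    }, numeric(1))
    worst <- min(worst, fisher_criterion(fit) - max(j_grid))
  }
  expect_gt(worst, -1e-6)
})

test_that("posterior matches the explicit Bayes density ratio", {
  set.seed(3)
  for (s in 1:20) {
    m0 <- rnorm(1); m1 <- m0 + runif(1, 0.5, 3)
    s0 <- runif(1, 0.3, 2); s1 <- runif(1, 0.3, 2)
    z0 <- rnorm(50, m0, s0); z1 <- rnorm(50, m1, s1)
    fit <- flda(matrix(c(z0, z1), ncol = 1), labels = rep(0:1, each = 50))
    zt <- rnorm(20, (m0 + m1) / 2, 2)
    p <- predict(fit, matrix(zt * sign(unname(fit$w)), ncol = 1))
    pm <- fit$projected$mean
    pv <- sqrt(fit$projected$var)
    zz <- zt * sign(unname(fit$w)) * unname(fit$w)
    direct <- dnorm(zz, pm[2], pv[2]) /
      (dnorm(zz, pm[2], pv[2]) + dnorm(zz, pm[1], pv[1]))
    expect_equal(p, direct, tolerance = 1e-10)
  }
})

test_that("posterior is 0.5 at the midpoint and saturates in the limits", {
  # symmetric classes with equal variances (mirror each class exactly)
  set.seed(11)
  z <- c(rnorm(200, -2, 1), rnorm(200, 2, 1))
  z <- c(z, -z)
  y <- c(rep(0:1, each = 200), rep(1:0, each = 200))
  fit <- flda(matrix(z, ncol = 1), labels = y, variance = "pooled")
  mid <- mean(fit$projected$mean)
  expect_equal(predict(fit, matrix(mid, 1, 1)), 0.5)
  expect_gt(predict(fit, matrix(100, 1, 1) * sign(unname(fit$w))), 1 - 1e-10)
  expect_lt(predict(fit, matrix(-100, 1, 1) * sign(unname(fit$w))), 1e-10)
  # tie at the midpoint classifies as target
  expect_equal(flda_classify(fit, matrix(mid, 1, 1)), 1L)
})

test_that("well-separated clouds are classified perfectly", {
  dat <- gaussian_features(200, 3, shift = c(f1 = 8), seed = 4)
  fit <- flda(dat)
  expect_equal(flda_classify(fit, dat), dat$label)
  # point at the class-1 training mean is labelled 1
  expect_equal(flda_classify(fit, fit$class_means["1", , drop = FALSE]), 1L)
})

test_that("classification is invariant to a global scale of X", {
  dat <- gaussian_features(50, 4, shift = c(f2 = 1.5), seed = 5)
  X <- feature_matrix(dat)
  f1 <- flda(X, labels = dat$label)
  f2 <- flda(X * 7, labels = dat$label)
  expect_equal(flda_classify(f1, X), flda_classify(f2, X * 7))
})

test_that("ridge -> 0 recovers the unregularised closed form", {
  set.seed(6)
  X <- rbind(matrix(rnorm(600), 300), matrix(rnorm(600), 300) + 1)
  y <- rep(0:1, each = 300)
  fit <- flda(X, labels = y, ridge = 1e-10)
  mu0 <- colMeans(X[y == 0, ]); mu1 <- colMeans(X[y == 1, ])
  C0 <- sweep(X[y == 0, ], 2, mu0); C1 <- sweep(X[y == 1, ], 2, mu1)
  w_exact <- solve(crossprod(C0) + crossprod(C1), mu1 - mu0)
  w_exact <- w_exact / sqrt(sum(w_exact^2))
  angle <- acos(pmin(1, abs(sum(w_exact * fit$w))))
  expect_lt(angle, 1e-8)
})

test_that("accuracy approaches Phi(Delta/2) for equal-covariance Gaussians", {
  set.seed(7)
  delta <- 2
  n <- 1e4
  X <- matrix(c(rnorm(n), rnorm(n) + delta), ncol = 1)
  y <- rep(0:1, each = n)
  fit <- flda(X, labels = y, variance = "pooled")
  acc <- mean(flda_classify(fit, X) == y)
  expect_lt(abs(acc - pnorm(delta / 2)), 0.03)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(flda(matrix(rnorm(6), ncol = 2), labels = c(0, 0, 1)),
               "at least 2 points")
  dat <- gaussian_features(10, 2)
  fit <- flda(dat)
  expect_error(predict(fit, dplyr::select(dat, -"f1")), "missing feature")
  expect_error(predict(fit, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("tidy and glance expose the projection and the criterion", {
  dat <- gaussian_features(30, 3, shift = c(f3 = 2), seed = 8)
  fit <- flda(dat)
  td <- tidy(fit)
  expect_equal(td$feature, c("f1", "f2", "f3"))
  expect_equal(sum(td$weight^2), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$n_features, 3L)
  expect_gt(gl$criterion, 0)
})

test_that("model JSON serialisation round-trips posterior scoring", {
  dat <- gaussian_features(30, 3, shift = c(f1 = 2), seed = 9)
  fit <- flda(dat)
  path <- withr::local_tempfile(fileext = ".json")
  write_flda_json(fit, path)
  back <- read_flda_json(path)
  expect_equal(predict(back, dat), predict(fit, dat), tolerance = 1e-12)
})
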
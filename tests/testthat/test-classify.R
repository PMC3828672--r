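test_that("discriminant predictions match brute-force Bayes evaluation", {
  set.seed(51)
  n <- 300
  x <- rbind(matrix(rnorm(n * 2, 0, 1), ncol = 2),
             matrix(rnorm(n * 2, 2, 1.5), ncol = 2))
  y <- factor(rep(c("hit", "nohit"), each = n), levels = c("hit", "nohit"))
  m <- fit_qda(x, y)
  pts <- matrix(rnorm(200, 1, 2), ncol = 2)
  pred <- predict_qda(m, pts)
  # independent route: evaluate the two fitted Gaussian densities directly
  dens <- vapply(m$classes, function(cl) {
    f <- m$fits[[cl]]
    S <- t(f$chol) %*% f$chol
    vapply(seq_len(nrow(pts)), function(i) {
      v <- pts[i, ] - f$mean
      log(f$prior) - 0.5 * f$logdet -
        0.5 * drop(v %*% solve(S, v)) - log(2 * pi)
    }, numeric(1))
  }, numeric(nrow(pts)))
  oracle <- factor(m$classes[max.col(dens)], levels = m$classes)
  expect_identical(pred, oracle)
})

test_that("class means classify to their class and ties follow the prior", {
  set.seed(52)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 4), ncol = 2))
  y <- factor(rep(c("a", "b"), each = 50))
  m <- fit_qda(x, y)
  mu_a <- m$fits[["a"]]$mean
  mu_b <- m$fits[["b"]]$mean
  expect_identical(as.character(predict_qda(m, rbind(mu_a))), "a")
  expect_identical(as.character(predict_qda(m, rbind(mu_b))), "b")
  # exactly mirrored classes: the midpoint is a perfect tie, broken to
  # the first class in level order when priors are equal
  x3 <- matrix(c(-1, -2, -3, 1, 2, 3), ncol = 1)
  y3 <- factor(rep(c("a", "b"), each = 3))
  m3 <- fit_qda(x3, y3)
  sc <- qda_scores(m3, matrix(0))
  expect_identical(unname(sc[1, "a"]), unname(sc[1, "b"]))
  expect_identical(as.character(predict_qda(m3, matrix(0))), "a")
  expect_error(fit_qda(x3, factor(rep("a", 6))), "2 classes")
})

test_that("scalar model reproduces the analytic quadratic boundary", {
  set.seed(53)
  x <- matrix(c(rnorm(4000, 0, 1), rnorm(4000, 0, 2)), ncol = 1)
  y <- factor(rep(c("n", "w"), each = 4000))
  m <- fit_qda(x, y)
  # closed-form boundary points of equal log densities for the fitted
  # parameters: solve a x^2 + b x + c = 0
  p <- lapply(m$fits, function(f) {
    list(mu = f$mean, s2 = drop(f$chol)^2, lp = log(f$prior))
  })
  a <- 1 / p$w$s2 - 1 / p$n$s2
  b <- 2 * (p$n$mu / p$n$s2 - p$w$mu / p$w$s2)
  cc <- p$w$mu^2 / p$w$s2 - p$n$mu^2 / p$n$s2 +
    log(p$w$s2) - log(p$n$s2) + 2 * (p$w$lp - p$n$lp)
  roots <- sort(Re(polyroot(c(cc, b, a))))
  # at the roots the two discriminant scores coincide
  sc <- qda_scores(m, matrix(roots, ncol = 1))
  expect_equal(sc[, 1], sc[, 2], tolerance = 1e-8)
  # just inside/outside the roots the narrow class wins/loses
  mid <- mean(roots)
  expect_identical(as.character(predict_qda(m, matrix(mid))), "n")
  out <- roots[2] + 1
  expect_identical(as.character(predict_qda(m, matrix(out))), "w")
})

test_that("duplicate rows are handled by covariance regularization", {
  x <- matrix(rep(c(1, 2), each = 6), ncol = 2)[c(1:3, 1:3), ]
  x <- rbind(x, x + 5)
  y <- factor(rep(c("a", "b"), each = 6))
  m <- fit_qda(x, y)
  expect_true(all(is.finite(qda_scores(m, x))))
  pred <- predict_qda(m, x)
  expect_identical(as.character(pred), as.character(y))
})

test_that("agreement with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  set.seed(54)
  x <- rbind(matrix(rnorm(400, 0, 1), ncol = 2),
             matrix(rnorm(400, 1.5, 1.3), ncol = 2))
  y <- factor(rep(c("hit", "nohit"), each = 200), levels = c("hit", "nohit"))
  m <- fit_qda(x, y)
  ref <- MASS::qda(x, y)
  pts <- matrix(rnorm(300, 0.7, 1.5), ncol = 2)
  expect_identical(as.character(predict_qda(m, pts)),
                   as.character(predict(ref, pts)$class))
})

test_that("confusion metrics reproduce hand-computed values", {
  m <- confusion_metrics(8, 2, 7, 3)
  expect_equal(m$error_pct, 25)
  expect_equal(m$sensitivity_pct, 80)
  expect_equal(m$specificity_pct, 70)
  expect_equal(m$accuracy_pct, 75)
})

test_that("cross-validation separates what is separable and is reproducible", {
  set.seed(55)
  x <- rbind(matrix(rnorm(200, 0, 0.5), ncol = 2),
             matrix(rnorm(200, 10, 0.5), ncol = 2))
  y <- factor(rep(c("hit", "nohit"), each = 100), levels = c("hit", "nohit"))
  r <- crossval_5fold(x, y, seed = 3)
  expect_equal(r$mean_error_pct, 0)
  expect_equal(r$sensitivity_pct, 100)
  expect_equal(r$specificity_pct, 100)
  expect_equal(r$accuracy_pct + r$mean_error_pct, 100)
  r2 <- crossval_5fold(x, y, seed = 3)
  expect_identical(r$folds, r2$folds)
  expect_error(crossval_5fold(x[c(1:3, 101:103), ], y[c(1:3, 101:103)]),
               "at least 5")
})

test_that("cross-validated accuracy approaches the analytic Bayes accuracy", {
  set.seed(56)
  n <- 500
  x <- matrix(c(rnorm(n, 0, 1), rnorm(n, 2, 1)), ncol = 1)
  y <- factor(rep(c("hit", "nohit"), each = n), levels = c("hit", "nohit"))
  r <- crossval_5fold(x, y, seed = 4)
  bayes <- 100 * pnorm(1)  # equal spherical classes, means 0 and 2
  expect_lt(abs(r$accuracy_pct - bayes), 3)
})

test_that("shuffled labels give chance-level error", {
  set.seed(57)
  errs <- vapply(1:30, function(s) {
    x <- matrix(rnorm(200 * 3), ncol = 3)
    y <- factor(rep(c("hit", "nohit"), each = 100),
                levels = c("hit", "nohit"))
    crossval_5fold(x, y, seed = s)$mean_error_pct
  }, numeric(1))
  # 30 independent null datasets, 200 decisions each: the mean error is
  # within the 99% normal band around 50%
  half <- 100 * 2.576 * sqrt(0.25 / (30 * 200))
  expect_lt(abs(mean(errs) - 50), half + 2)  # +2 for fold-level correlation
})
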
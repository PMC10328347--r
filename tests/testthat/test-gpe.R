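test_that("a linear truth is recovered through the trend", {
  X <- matrix(seq(0, 1, length.out = 10), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- 2 * X[, 1]
  m <- gpe(X, y, nugget = "fixed", n_restarts = 2)
  expect_equal(unname(coef(m)), c(0, 2), tolerance = 1e-3)
  expect_equal(predict(m, matrix(0.5))$mean, 1, tolerance = 1e-3)
  # residual signal variance collapses when the trend explains the data
  expect_lt(exp(m$theta[["log_sf2"]]), 1e-2)
})

test_that("noise-free training points are interpolated to 1e-6", {
  set.seed(7)
  X <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- sin(6 * X[, 1]) * cos(4 * X[, 2])
  m <- gpe(X, y, nugget = "fixed", n_restarts = 3)
  p <- predict(m, X)
  expect_lt(max(abs(p$mean - y)) / diff(range(y)), 1e-6)
})

test_that("degenerate constant outputs are flagged and predicted flat", {
  X <- matrix(seq(0, 1, length.out = 8), ncol = 1)
  expect_warning(m <- gpe(X, rep(7, 8)), "constant")
  p <- predict(m, matrix(c(0.25, 0.9), ncol = 1))
  expect_equal(p$mean, c(7, 7))
  expect_equal(p$sd, c(0, 0))
})

test_that("input validation rejects bad training sets", {
  X <- matrix(runif(20), 10, 2)
  expect_error(gpe(X, c(runif(9), NA)), "finite")
  expect_error(gpe(X[1:3, ], runif(3)), "D \\+ 2")
  m <- gpe(X, rowSums(X), n_restarts = 1)
  expect_error(predict(m, matrix(runif(9), 3, 3)), "columns")
  p0 <- predict(m, X[0, , drop = FALSE])
  expect_equal(nrow(p0), 0)
})

test_that("the exponentiated quadratic kernel equals the signal variance at zero lag", {
  th <- c(log(0.3), log(0.2), log(2.5))
  x <- matrix(runif(2), 1, 2)
  K <- cardioemu:::gpe_kernel(x, x, th, "exp_quadratic")
  expect_equal(K[1, 1], 2.5)
  K2 <- cardioemu:::gpe_kernel(x, x, th, "matern52")
  expect_equal(K2[1, 1], 2.5)
})

test_that("posterior sd grows away from the training cloud", {
  set.seed(3)
  X <- matrix(runif(40), 20, 2)
  y <- sin(5 * X[, 1]) + X[, 2]
  m <- gpe(X, y, n_restarts = 2)
  grid <- as.matrix(expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1)))
  sd_in <- predict(m, grid)$sd
  p_far <- predict(m, matrix(c(4, 4), 1, 2))
  expect_true(p_far$extrapolated)
  expect_gte(p_far$sd, max(sd_in))
})

test_that("posterior draws match the predictive moments and the seed", {
  set.seed(1)
  X <- matrix(runif(30), 15, 2)
  y <- X[, 1]^2 + 0.5 * X[, 2]
  m <- gpe(X, y, n_restarts = 2)
  xs <- matrix(c(0.31, 0.62), 1, 2)
  p <- predict(m, xs)
  dr <- simulate(m, nsim = 1000, seed = 5, newdata = xs)
  expect_lt(abs(mean(dr) - p$mean), 3 * p$sd / sqrt(1000) + 1e-12)
  expect_equal(sd(dr), p$sd, tolerance = 0.15)
  expect_identical(simulate(m, 5, seed = 9, newdata = xs),
                   simulate(m, 5, seed = 9, newdata = xs))
  # a zero-sd point yields identical draws
  expect_warning(mc <- gpe(X, rep(2, 15)), "constant")
  dc <- simulate(mc, 20, seed = 2, newdata = xs)
  expect_true(all(dc == 2))
  expect_error(simulate(m, 0, seed = 1, newdata = xs))
})

test_that("cross-validation scores match hand arithmetic", {
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0)   # RSS = TSS = 2
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ise_score(c(1, 2, 3), c(1, 2, 10), c(1, 1, 1)),
               100 * 2 / 3)
  expect_equal(ise_score(c(1, 2), c(1, 2), c(0.1, 0.1)), 100)
})

test_that("k-fold cross-validation is seeded and bounded", {
  set.seed(2)
  X <- matrix(runif(150), 50, 3)
  y <- smooth3(X)
  cv <- cross_validate(X, y, k_folds = 5, seed = 4, n_restarts = 2)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(cv$folds$r2 <= 1))
  expect_true(all(cv$folds$ise >= 0 & cv$folds$ise <= 100))
  cv2 <- cross_validate(X, y, k_folds = 5, seed = 4, n_restarts = 2)
  expect_identical(cv$folds, cv2$folds)
  expect_error(cross_validate(X, y, k_folds = 1, seed = 1), "k_folds")
})

test_that("kernel choice barely moves held-out accuracy on a smooth function", {
  set.seed(11)
  X <- matrix(runif(600), 200, 3)
  y <- smooth3(X)
  cv_eq <- cross_validate(X, y, k_folds = 5, seed = 1, n_restarts = 1,
                          kernel = "exp_quadratic")
  cv_m <- cross_validate(X, y, k_folds = 5, seed = 1, n_restarts = 1,
                         kernel = "matern52")
  expect_lt(abs(cv_eq$mean_r2 - cv_m$mean_r2), 0.05)
})
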
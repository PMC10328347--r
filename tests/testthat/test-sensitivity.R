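test_that("an additive single-variable function puts all variance on it", {
  sp <- unit_space(3)
  r <- sobol_total_effects(function(X) X[, 1], sp, n_base = 2048, seed = 2)
  expect_equal(unname(r$total_effects[, 1]), c(1, 0, 0), tolerance = 0.02)
  expect_equal(unname(r$first_order[, 1]), c(1, 0, 0), tolerance = 0.02)
})

test_that("Ishigami total effects match the closed-form decomposition", {
  sp <- unit_space(3, lower = -pi, upper = pi)
  r <- sobol_total_effects(function(X) ishigami(X), sp, n_base = 8192,
                           seed = 5)
  expect_equal(unname(r$total_effects[, 1]), ishigami_total_effects(),
               tolerance = 0.03)
  # interactions present: total effects sum beyond 1
  expect_gt(sum(r$total_effects[, 1]), 1)
})

test_that("the Jansen estimator agrees with brute-force double-loop MC", {
  f <- function(X) X[, 1]^2 + 2 * X[, 2] * X[, 3] + 0.5 * X[, 3]
  sp <- unit_space(3)
  r <- sobol_total_effects(f, sp, n_base = 4096, seed = 7)
  bf <- brute_force_total_effects(f, 3, n_outer = 400, n_inner = 400,
                                  seed = 8)
  se <- 1 / sqrt(400)  # conservative MC scale for the double loop
  expect_true(all(abs(r$total_effects[, 1] - bf) < 3 * se))
})

test_that("emulated total effects average over posterior draws", {
  set.seed(4)
  sp <- unit_space(3)
  X <- unclass(latin_hypercube(sp, 60, seed = 1))
  models <- list(y = gpe(X, smooth3(X), n_restarts = 2))
  r <- sobol_total_effects(models, sp, n_base = 4096, n_draws = 25, seed = 3)
  exact <- sobol_total_effects(function(X) smooth3(X), sp, n_base = 16384,
                               seed = 9)
  expect_equal(unname(r$total_effects[, 1]),
               unname(exact$total_effects[, 1]), tolerance = 0.05)
  expect_true(all(r$total_effects_sd >= 0))
})

test_that("across-draw dispersion shrinks as the training set grows", {
  sp <- unit_space(3)
  disp <- vapply(c(25, 100), function(n) {
    X <- unclass(latin_hypercube(sp, n, seed = 1))
    m <- list(y = gpe(X, smooth3(X), n_restarts = 1))
    r <- sobol_total_effects(m, sp, n_base = 256, n_draws = 20, seed = 2)
    mean(r$total_effects_sd)
  }, numeric(1))
  expect_lt(disp[2], disp[1])
})

test_that("constant outputs yield zero effects with a warning", {
  sp <- unit_space(2)
  expect_warning(r <- sobol_total_effects(function(X) rep(3, nrow(X)), sp,
                                          n_base = 64, seed = 1),
                 "constant")
  expect_true(all(r$total_effects == 0))
  expect_error(rank_and_retain(r), "zero")
})

test_that("ranking retains the minimal prefix reaching the threshold", {
  fake <- structure(list(total_effects = matrix(c(0.6, 0.3, 0.1), 3, 1,
                                                dimnames = list(c("p1", "p2", "p3"), "y"))),
                    class = "sobol_result")
  rk <- rank_and_retain(fake, 0.9)
  expect_identical(rk$retained, c("p1", "p2"))
  expect_equal(sum(rk$normalized_max), 1, tolerance = 1e-9)
  # four equal scores at 0.9 retain all four
  eq <- structure(list(total_effects = matrix(0.2, 4, 1,
                                              dimnames = list(paste0("q", 1:4), "y"))),
                  class = "sobol_result")
  expect_length(rank_and_retain(eq, 0.9)$retained, 4)
  # ties break by the stable parameter order
  tie <- structure(list(total_effects = matrix(c(0.5, 0.5, 0.1), 3, 1,
                                               dimnames = list(c("a", "b", "c"), "y"))),
                   class = "sobol_result")
  expect_identical(rank_and_retain(tie, 0.5)$order[1:2], c("a", "b"))
})

test_that("signed effects carry the trend coefficient sign", {
  set.seed(6)
  sp <- unit_space(2)
  X <- unclass(latin_hypercube(sp, 40, seed = 2))
  y_up <- 3 * X[, 1] + 0.2 * X[, 2]
  y_dn <- -2 * X[, 1] + 0.1 * X[, 2]
  models <- list(up = gpe(X, y_up, n_restarts = 1),
                 dn = gpe(X, y_dn, n_restarts = 1))
  r <- sobol_total_effects(models, sp, n_base = 256, n_draws = 5, seed = 1)
  s <- signed_effects(r, models)
  expect_gt(s["x1", "up"], 0)
  expect_lt(s["x1", "dn"], 0)
  # signs match finite-difference slopes of the truth at the box centre
  expect_equal(sign(s["x1", "up"]), sign(3))
  expect_equal(sign(s["x1", "dn"]), sign(-2))
})

test_that("display normalisation scales each output column to [0, 1]", {
  S <- matrix(c(0.4, 0.2, -0.01, 0.8), 2, 2,
              dimnames = list(c("a", "b"), c("y1", "y2")))
  fake <- structure(list(total_effects = S), class = "sobol_result")
  N <- normalize_effects(fake)
  expect_equal(unname(apply(N, 2, max)), c(1, 1))
  expect_true(all(N >= 0))
})

test_that("plausibility screening masks rows through emulator constraints", {
  sp <- unit_space(2)
  X <- unclass(latin_hypercube(sp, 200, seed = 1))
  # no constraints: everything passes
  expect_true(all(screen_samples(X, list())))
  # constraint: y = x1 must match 0.25 +- 0.01
  Xt <- unclass(latin_hypercube(unit_space(1), 30, seed = 2))
  colnames(Xt) <- "x1"
  m <- gpe(Xt, Xt[, 1], n_restarts = 1)
  ct <- list(models = list(y = m), targets = hm_targets("y", 0.25, 0.01),
             params = "x1")
  mask <- screen_samples(X, list(ct), I_th = 3)
  expect_true(all(abs(X[mask, 1] - 0.25) < 0.05))
  expect_identical(mask, screen_samples(X, list(ct), I_th = 3))
  # growing the base sequence finds enough plausible rows
  pl <- plausible_base_sequence(sp, list(ct), n_required = 50,
                                n_base = 200, seed = 3)
  expect_gt(nrow(pl), 50)
  # unreachable target: rejection with diagnostics
  bad <- list(models = list(y = m), targets = hm_targets("y", 50, 0.001),
              params = "x1")
  expect_error(plausible_base_sequence(sp, list(bad), n_required = 50,
                                       n_base = 100, max_iter = 2,
                                       seed = 4))
  # overlapping constraint blocks are rejected
  expect_error(plausible_base_sequence(sp, list(ct, ct), seed = 1),
               "overlap")
})
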
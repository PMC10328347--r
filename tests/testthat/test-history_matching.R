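test_that("implausibility arithmetic matches hand cases", {
  tg <- hm_targets("y", 2, 1)
  expect_equal(implausibility(matrix(2, dimnames = list(NULL, "y")),
                              matrix(0), tg), 0)
  expect_equal(implausibility(matrix(5, dimnames = list(NULL, "y")),
                              matrix(0), tg), 3)
  # combined emulator and observation variance in the denominator
  expect_equal(implausibility(matrix(5, dimnames = list(NULL, "y")),
                              matrix(1), tg), 3 / sqrt(2))
  # max rule over outputs
  tg2 <- hm_targets(c("y1", "y2"), c(0, 0), c(1, 1))
  m <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("y1", "y2")))
  expect_equal(implausibility(m, matrix(0, 1, 2), tg2), 2)
  expect_error(implausibility(matrix(1, dimnames = list(NULL, "zz")),
                              matrix(0), tg), "zz")
  expect_error(hm_targets("y", 1, 0), "sigma")
})

test_that("waves concentrate the plausible region on the target pre-image", {
  tg <- hm_targets("y", 0.25, 0.01)
  w1 <- hm_wave(toy_hm_space(), toy_hm_sim, tg, I_th = 3, n_test = 2000,
                n_simul = 12, seed = 1, n_restarts = 2)
  w2 <- hm_wave(w1, toy_hm_sim, tg, n_test = 2000, seed = 2,
                n_restarts = 2)
  pl <- unclass(w2$cloud)[w2$plausible, 1]
  # analytic pre-image: |x| in sqrt(0.25 +- 3 sigma)
  expect_true(all(abs(pl) > sqrt(0.25 - 3.5 * 0.01)))
  expect_true(all(abs(pl) < sqrt(0.25 + 3.5 * 0.01)))
  expect_true(any(pl > 0) && any(pl < 0))
  expect_equal(w2$wave, 2)
  expect_equal(nrow(w2$X), 24)
})

test_that("an infinite threshold degenerates the wave to re-training", {
  tg <- hm_targets("y", 0.25, 0.01)
  w <- hm_wave(toy_hm_space(), toy_hm_sim, tg, I_th = Inf, n_test = 500,
               n_simul = 10, seed = 3, n_restarts = 1)
  expect_true(all(w$plausible))
  expect_equal(w$diagnostics$percent_plausible, 100)
})

test_that("sigma limits drive the plausible fraction to all or nothing", {
  w <- hm_wave(toy_hm_space(), toy_hm_sim,
               hm_targets("y", 0.25, 1e6), I_th = 3, n_test = 500,
               n_simul = 10, seed = 4, n_restarts = 1)
  expect_equal(mean(w$plausible), 1)
  w0 <- hm_wave(toy_hm_space(), toy_hm_sim,
                hm_targets("y", 25, 1e-6), I_th = 3, n_test = 500,
                n_simul = 10, seed = 4, n_restarts = 1)
  expect_true(w0$exhausted)
  expect_equal(mean(w0$plausible), 0)
  expect_error(hm_wave(w0, toy_hm_sim, hm_targets("y", 25, 1e-6)),
               "exhausted")
})

test_that("diagnostics summarise the test cloud and ignore its order", {
  tg <- hm_targets("y", 0.25, 0.05)
  w <- hm_wave(toy_hm_space(), toy_hm_sim, tg, n_test = 400, n_simul = 10,
               seed = 5, n_restarts = 1)
  d <- wave_diagnostics(w)
  expect_gte(d$max_I, d$mean_I)
  expect_gte(d$max_v_ratio, d$mean_v_ratio)
  expect_true(d$percent_plausible >= 0 && d$percent_plausible <= 100)
  perm <- with(w, {
    i <- sample(length(I))
    list(percent = 100 * mean(plausible[i]), mean_I = mean(I[i]))
  })
  expect_equal(perm$percent, d$percent_plausible)
  expect_equal(perm$mean_I, d$mean_I)
})

test_that("region intersection pairs disjoint blocks and truncates", {
  a <- matrix(1:6, 3, 2, dimnames = list(NULL, c("p1", "p2")))
  b <- matrix(1:15, 5, 3, dimnames = list(NULL, c("q1", "q2", "q3")))
  j <- intersect_regions(list(a, b), seed = 1)
  expect_equal(dim(j), c(3, 5))
  expect_identical(colnames(j), c("p1", "p2", "q1", "q2", "q3"))
  # marginals preserved: each block's rows are rows of the original cloud
  expect_true(all(j[, "p1"] %in% a[, "p1"]))
  expect_true(all(j[, "q3"] %in% b[, "q3"]))
  # row pairing within a block stays intact
  for (r in seq_len(3)) {
    i <- match(j[r, "p1"], a[, "p1"])
    expect_equal(unname(j[r, "p2"]), unname(a[i, "p2"]))
  }
  # single cloud plus empty extra is the identity up to row order
  only <- intersect_regions(list(a), extra_lhs = b[0, , drop = FALSE],
                            seed = 2)
  expect_equal(sort(only[, "p1"]), sort(a[, "p1"]))
  bad <- matrix(1, 2, 1, dimnames = list(NULL, "p1"))
  expect_error(intersect_regions(list(a, bad), seed = 1), "overlap")
})

test_that("larger marginal samples keep their distribution under pairing", {
  set.seed(9)
  a <- matrix(rbeta(500, 2, 5), 500, 1, dimnames = list(NULL, "u"))
  b <- matrix(runif(500), 500, 1, dimnames = list(NULL, "v"))
  j <- intersect_regions(list(a, b), seed = 3)
  expect_gt(suppressWarnings(ks.test(j[, "u"], a[, "u"]))$p.value, 1e-6)
  expect_equal(mean(j[, "u"]), mean(a[, "u"]), tolerance = 1e-12)
})

test_that("threshold schedules are validated against the 3-sigma floor", {
  expect_identical(final_threshold_check(c(5, 4, 3)), c(5, 4, 3))
  expect_identical(final_threshold_check(3), 3)
  expect_error(final_threshold_check(c(3, 4)), "non-increasing")
  expect_warning(out <- final_threshold_check(c(6, 5)), "appending")
  expect_identical(out, c(6, 5, 3))
})
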
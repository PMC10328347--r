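test_that("the calcium transient peaks at the stated amplitude", {
  ca <- simulate_calcium(calcium_params(ca_dias = 0.1, ca_amp = 0.8),
                         bcl = 854, dt = 0.02)
  expect_equal(max(ca$value), 0.9, tolerance = 1e-5)
  expect_equal(ca$value[1], 0.1, tolerance = 1e-5)
  expect_true(attr(ca, "converged"))
  # the pacing grid honours the cycle length
  expect_equal(nrow(ca), 854 / 0.02)
  expect_equal(ca$t[2] - ca$t[1], 0.02)
})

test_that("amplitude scaling is linear and decay scaling stretches the tail", {
  c1 <- simulate_calcium(calcium_params(amp_scale = 1), bcl = 500, dt = 0.05)
  c2 <- simulate_calcium(calcium_params(amp_scale = 2), bcl = 500, dt = 0.05)
  f1 <- transient_features(c1); f2 <- transient_features(c2)
  expect_equal(f2[["amplitude"]], 2 * f1[["amplitude"]], tolerance = 1e-3)
  expect_equal(f2[["time_to_peak"]], f1[["time_to_peak"]], tolerance = 0.06)
  c3 <- simulate_calcium(calcium_params(decay_scale = 1.8), bcl = 500,
                         dt = 0.05)
  expect_gt(transient_features(c3)[["duration_90"]], f1[["duration_90"]])
  expect_error(calcium_params(tau_rise = 80, tau_decay = 60), "tau_rise")
  expect_error(calcium_params(ca_amp = -1), "positive")
})

test_that("sustained activation reaches the algebraic crossbridge steady state", {
  lp <- land_params()
  ca <- simulate_calcium(calcium_params(), bcl = 854, dt = 0.02)
  ca$value <- rep(5, nrow(ca))          # saturating but integrable
  tn <- simulate_tension(ca, lp, n_beats = 10)
  st <- attr(tn, "states")
  fin <- st[nrow(st), ]
  expect_equal(fin[4], lp$r_s, tolerance = 0.01)          # S -> r_s
  expect_equal(fin[3] / fin[4], lp$r_w, tolerance = 0.01) # W/S -> r_w
  expect_equal(max(tn$value) / lp$T_ref, 1, tolerance = 0.01)
  # sub-saturating constant permissive fraction: match the flux-balance
  # steady state of the chain
  ca2 <- ca; ca2$value <- rep(0.55, nrow(ca2))  # Ca = ca50
  tn2 <- simulate_tension(ca2, lp, n_beats = 12)
  st2 <- attr(tn2, "states")
  p_eq <- st2[nrow(st2), 2]
  pred <- crossbridge_steady_state(p_eq, lp)
  expect_equal(unname(st2[nrow(st2), 4]), unname(pred["S"]),
               tolerance = 0.02)
})

test_that("diastolic calcium far below ca50 suppresses tension", {
  lp <- land_params()
  ca <- simulate_calcium(calcium_params(), bcl = 500, dt = 0.02)
  ca$value <- rep(0.1, nrow(ca))
  tn <- simulate_tension(ca, lp, n_beats = 6)
  expect_lt(max(tn$value), 0.05 * lp$T_ref)
})

test_that("unstable integration is rejected with a step report", {
  lp <- land_params()
  ca <- simulate_calcium(calcium_params(), bcl = 200, dt = 0.02)
  ca$value <- rep(500, nrow(ca))        # troponin ODE far too stiff
  expect_error(simulate_tension(ca, lp), "negative state")
})

test_that("velocity dependence damps tension within [0, 1]", {
  lp <- land_params()
  ca <- simulate_calcium(calcium_params(), bcl = 500, dt = 0.05)
  t0 <- simulate_tension(ca, lp)
  tv <- simulate_tension(ca, lp, velocity = rep(0.05, nrow(ca)))
  expect_lt(max(tv$value), max(t0$value))
  th <- simulate_tension(ca, lp, velocity = rep(10, nrow(ca)))
  expect_gte(min(th$value), 0)          # factor clamped at 0
})

test_that("transient features match simple shapes", {
  tri <- data.frame(t = seq(0, 100, by = 1),
                    value = c(seq(0, 1, length.out = 51),
                              seq(1, 0, length.out = 51)[-1]))
  f <- transient_features(tri)
  expect_equal(f[["time_to_peak"]], 50)
  expect_equal(f[["peak"]], 1)
  expect_equal(f[["amplitude"]], 1)
  expect_equal(f[["duration_90"]], 95, tolerance = 0.03)
  cst <- data.frame(t = 0:50, value = rep(2, 51))
  fc <- transient_features(cst)
  expect_equal(fc[["amplitude"]], 0)
  expect_equal(fc[["duration_90"]], 0)
})

test_that("features are stable under time-grid refinement", {
  f_at <- function(dt) {
    ca <- simulate_calcium(calcium_params(), bcl = 500, dt = dt)
    transient_features(simulate_tension(ca, land_params()))
  }
  f1 <- f_at(0.1); f2 <- f_at(0.02)
  for (k in c("peak", "time_to_peak", "duration_90"))
    expect_equal(f1[[k]], f2[[k]], tolerance = 0.01)
})

test_that("steady-state pacing has bounded beat-to-beat drift", {
  ca <- simulate_calcium(calcium_params(tau_decay = 120), bcl = 400,
                         dt = 0.05, n_beats = 60)
  expect_true(attr(ca, "converged"))
  tn <- simulate_tension(ca, land_params(), n_beats = 15)
  # re-integrating one more beat from the final state changes the peak
  # by less than 0.1%
  tn2 <- simulate_tension(ca, land_params(), n_beats = 16)
  expect_lt(abs(max(tn2$value) - max(tn$value)) / max(tn$value), 0.001)
})
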
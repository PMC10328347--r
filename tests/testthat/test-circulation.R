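run_with <- function(..., cp_fn = NULL, n_beats = 5) {
  pars <- circ_params(...)
  cpas <- if (is.null(cp_fn)) default_chamber_passive(pars)
          else cp_fn(pars)
  run_beats(build_circuit(pars, cpas, cached_drivers()), n_beats = n_beats)
}

test_that("circuit construction validates its inputs", {
  expect_error(circ_params(R_sys = 5), "\\[1, 4\\]")
  expect_error(circ_params(q_ref = -1), "positive")
  drv <- cached_drivers()
  bad <- drv
  attr(bad$LV, "bcl") <- 900
  expect_error(build_circuit(circ_params(), tension_drivers = bad),
               "cycle length")
})

test_that("a zero drive stays at the passive rest state", {
  drv <- cached_drivers()
  zero <- lapply(drv, function(d) { d$value[] <- 0; d })
  circ <- build_circuit(circ_params(), tension_drivers = zero)
  run <- run_beats(circ, n_beats = 3, init = rest_state(circ, 5))
  tr <- run$traces
  # an equilibrium: no ejection, flows at numerical-residual level (the
  # sqrt valve law amplifies the equilibrium solve's ~1e-4 mmHg residual)
  q <- as.matrix(tr[, grep("^q_", names(tr))])
  expect_lt(max(abs(q)), 5)              # vs ~500 mL/s systolic flows
  expect_lt(max(abs(tr$V_LV - tr$V_LV[1])), 0.01)
  # perturbing away from rest sets up flows that relax, never eject
  init2 <- rest_state(circ, 5)
  init2["V_LV"] <- init2["V_LV"] + 20
  run2 <- run_beats(circ, n_beats = 6, init = init2)
  expect_true(run2$success)
  qs <- abs(run2$traces$q_MV) + abs(run2$traces$q_sys)
  b1 <- max(qs[run2$traces$time <= 854])
  b6 <- max(qs[run2$traces$time > 5 * 854])
  expect_lt(b6, b1)
})

test_that("closed-loop volume is conserved to 0.01% per beat", {
  run <- run_with()
  expect_true(run$success)
  tr <- run$traces
  tot <- rowSums(tr[, c("V_LV", "V_RV", "V_LA", "V_RA",
                        "V_Ao", "V_Pa", "V_Ve", "V_Pve")])
  beat_marks <- seq(1, nrow(tr), by = 854)
  expect_lt(max(abs(diff(tot[beat_marks]))) / tot[1], 1e-4)
})

test_that("left and right stroke volumes balance at steady state", {
  f <- pv_features(run_with())
  sv_l <- f[["EDV_LV"]] - f[["ESV_LV"]]
  sv_r <- f[["EDV_RV"]] - f[["ESV_RV"]]
  expect_lt(abs(sv_l - sv_r) / sv_l, 0.05)
})

test_that("all twenty features are finite at the default point", {
  f <- pv_features(run_with())
  expect_length(f, 20)
  expect_true(all(is.finite(f)))
  expect_gte(f[["EDV_LV"]], f[["ESV_LV"]])
  expect_gte(f[["EDV_RV"]], f[["ESV_RV"]])
  expect_gte(f[["p_max_LV"]], f[["EDP_LV"]])
})

test_that("afterload and stiffness move the features in the expected direction", {
  f0 <- pv_features(run_with())
  f_rs <- pv_features(run_with(R_sys = 2))
  f_rp <- pv_features(run_with(R_pulm = 2))
  f_av <- pv_features(run_with(
    cp_fn = function(p) default_chamber_passive(p, a_V = 1.5)))
  # systemic resistance raises LV afterload
  expect_gt(f_rs[["p_max_LV"]], f0[["p_max_LV"]])
  # pulmonary resistance raises RV afterload and preload, starves LA filling
  expect_gt(f_rp[["p_max_RV"]], f0[["p_max_RV"]])
  expect_gt(f_rp[["EDV_RV"]], f0[["EDV_RV"]])
  expect_lt(f_rp[["EDV_vwave_LA"]], f0[["EDV_vwave_LA"]])
  # stiffer ventricles eject less
  expect_gt(f_av[["ESV_LV"]], f0[["ESV_LV"]])
  expect_gt(f_av[["ESV_RV"]], f0[["ESV_RV"]])
})

test_that("the pericardium mediates opposite-signed EDV responses", {
  dilate <- function(p) default_chamber_passive(p, V0_LV = 65)
  resp <- function(kp) {
    f1 <- pv_features(run_with(k_peri = kp))
    f2 <- pv_features(run_with(k_peri = kp, cp_fn = dilate))
    c(dLV = f2[["EDV_LV"]] - f1[["EDV_LV"]],
      dRV = f2[["EDV_RV"]] - f1[["EDV_RV"]])
  }
  hi <- resp(2); lo <- resp(0.5)
  expect_gt(hi[["dLV"]], 0)
  expect_lt(hi[["dRV"]], 0)             # opposition at the stiff bound
  expect_lt(abs(lo[["dRV"]]), abs(hi[["dRV"]]))  # weaker when compliant
})

test_that("extreme parameter corners either fail cleanly or complete", {
  drv <- default_tension_drivers(854,
                                 ventricular = land_params(T_ref = 30),
                                 atrial = land_params(T_ref = 15))
  run <- run_beats(build_circuit(circ_params(R_sys = 4),
                                 tension_drivers = drv), n_beats = 5)
  expect_type(run$success, "logical")   # failure is data, not an error
  if (!run$success) expect_error(pv_features(run), "failed")
})

test_that("feature extraction recovers known extrema from traces", {
  run <- run_with()
  bcl <- 854
  n <- nrow(run$traces)
  idx <- (n - bcl):n
  # replace the last-beat LV pressure with a linear ramp: dp/dt = slope
  run2 <- run
  slope <- 0.37
  run2$traces$p_LV[idx] <- slope * seq_along(idx)
  f2 <- pv_features(run2)
  expect_equal(f2[["dpdt_max_LV"]], slope, tolerance = 1e-9)
  expect_equal(f2[["dpdt_min_LV"]], slope, tolerance = 1e-9)
  # replace the LV volume with a sinusoid of known extrema
  run3 <- run
  tau <- seq_along(idx) - 1
  run3$traces$V_LV[idx] <- 100 + 30 * sin(2 * pi * tau / bcl)
  f3 <- pv_features(run3)
  expect_equal(f3[["ESV_LV"]], 70, tolerance = 1e-5)
})

test_that("a vanishing activation spread reduces the drive to a shift", {
  drv <- cached_drivers()
  act <- list(LV = list(onset = 150, tat = 1e-6),
              RV = list(onset = 150, tat = 1e-6),
              LA = list(onset = 0, tat = 1e-6),
              RA = list(onset = 0, tat = 1e-6))
  circ <- build_circuit(circ_params(), tension_drivers = drv,
                        activation = act)
  tg <- seq(0, 854, length.out = nrow(circ$drive) + 1)[-(nrow(circ$drive) + 1)]
  f <- approxfun(c(drv$LV$t, 854), c(drv$LV$value, drv$LV$value[1]),
                 rule = 2)
  expect_equal(circ$drive[, "LV"], f((tg - 150) %% 854), tolerance = 1e-3)
})
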
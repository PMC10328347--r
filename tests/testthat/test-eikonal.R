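strip_grid <- function(nx, ny, h, label = "ventricular-myo",
                       fib = c(1, 0)) {
  labeled_grid(c(nx, ny), h, rep(label, nx * ny),
               matrix(fib, nx * ny, 2, byrow = TRUE))
}

test_that("velocity fields encode the transversely isotropic speeds", {
  g <- strip_grid(10, 4, 0.5)
  f <- build_velocity_field(g, cv_f_v = 0.6, k_ft_v = 0.4)
  expect_equal(unique(f$cf), 0.6)
  expect_equal(unique(f$ct), 0.24)
  iso <- build_velocity_field(g, cv_f_v = 0.6, k_ft_v = 1)
  expect_equal(iso$ct, iso$cf)
  expect_error(build_velocity_field(g, cv_f_v = -1), "> 0")
  expect_error(build_velocity_field(g, cv_f_v = 0.6, k_ft_v = 1.2),
               "anisotropy")
  expect_error(build_velocity_field(g, cv_f_v = 0.6, k_fec = 0.5), ">= 1")
})

test_that("fast-region scaling applies only inside the labelled region", {
  g <- two_slab_geometry(nx = 40, ny = 30, h = 0.5)
  f <- build_velocity_field(g, cv_f_v = 0.5, cv_f_a = 0.7, k_fec = 2,
                            k_bb = 3)
  expect_equal(unique(f$cf[g$labels == "FEC"]), 1.0)
  expect_equal(unique(f$cf[g$labels == "ventricular-myo"]), 0.5)
  expect_equal(unique(f$cf[g$labels == "BB"]), 2.1)
  expect_equal(unique(f$cf[g$labels == "atrial-myo"]), 0.7)
  expect_false(any(f$conducting[g$labels == "AV-insulation"]))
})

test_that("homogeneous isotropic fronts match t = d / c within 2%", {
  h <- 0.5
  g <- strip_grid(125, 25, h)
  f <- build_velocity_field(g, cv_f_v = 0.6, k_ft_v = 1)
  m <- solve_eikonal(g, f, data.frame(node = 1, t0 = 0))
  # along the axis (60 mm) and along the diagonal
  n_ax <- cardioemu:::node_index(g, 121, 1)
  expect_equal(m[n_ax], 60 / 0.6, tolerance = 0.02)
  n_dg <- cardioemu:::node_index(g, 121, 25)
  expect_equal(m[n_dg], sqrt(60^2 + 12^2) / 0.6, tolerance = 0.02)
  # causality: nothing earlier than the source
  expect_gte(min(m), 0)
})

test_that("anisotropic straight rays match the metric distance within 2%", {
  h <- 0.5
  g <- strip_grid(30, 60, h)               # fibres along x
  f <- build_velocity_field(g, cv_f_v = 0.6, k_ft_v = 0.4)
  m <- solve_eikonal(g, f, data.frame(node = 1, t0 = 0))
  # cross-fibre: 24 mm along y at speed 0.24 -> 100 ms
  expect_equal(m[cardioemu:::node_index(g, 1, 49)], 100, tolerance = 0.02)
  # along fibre: 12 mm at 0.6 -> 20 ms
  expect_equal(m[cardioemu:::node_index(g, 25, 1)], 20, tolerance = 0.02)
})

test_that("multi-source solutions are the pointwise minimum", {
  g <- strip_grid(60, 20, 0.5)
  f <- build_velocity_field(g, cv_f_v = 0.6, k_ft_v = 0.4)
  s1 <- data.frame(node = 1, t0 = 0)
  s2 <- data.frame(node = g$n, t0 = 50)
  mA <- solve_eikonal(g, f, s1)
  mB <- solve_eikonal(g, f, s2)
  mAB <- solve_eikonal(g, f, rbind(s1, s2))
  d <- pmin(mA, mB) - mAB
  # exact superposition away from the collision of the two fronts
  away <- abs(mA - mB) > 2
  expect_lt(max(abs(d[away])), 1e-6)
  # at the collision band the union solution may undercut by O(h)
  expect_gte(min(d), -1e-9)
  expect_lt(max(d), g$h)
})

test_that("the error shrinks when the grid is refined", {
  err_at <- function(h) {
    nx <- round(30 / h) + 1
    g <- strip_grid(nx, 5, h)
    f <- build_velocity_field(g, cv_f_v = 0.5, k_ft_v = 0.7)
    m <- solve_eikonal(g, f, data.frame(node = 1, t0 = 0))
    coords <- node_coords(g)
    truth <- sqrt(coords[, 1]^2 / 0.5^2 + coords[, 2]^2 / 0.35^2)
    max(abs(m - truth))
  }
  e1 <- err_at(1.0); e2 <- err_at(0.5)
  expect_lt(e2, e1)
})

test_that("the grid solution never exceeds the graph-Dijkstra bound", {
  g <- strip_grid(25, 15, 1.0)
  f <- build_velocity_field(g, cv_f_v = 0.6, k_ft_v = 0.4)
  m <- solve_eikonal(g, f, data.frame(node = 1, t0 = 0))
  dj <- dijkstra_times(g, f, 1)
  expect_true(all(m <= dj + 1e-6))
})

test_that("dual-site initiation honours the AV delay and insulation", {
  g <- two_slab_geometry(nx = 40, ny = 30, h = 0.5)
  f <- build_velocity_field(g, cv_f_v = 0.6, cv_f_a = 0.7, k_fec = 2,
                            k_bb = 2)
  m <- dual_site_initiation(g, f, av_delay = 150)
  vent <- g$labels %in% c("ventricular-myo", "FEC")
  atr <- g$labels %in% c("atrial-myo", "BB")
  expect_equal(min(m[vent]), 150)
  expect_equal(min(m[atr]), 0)
  # the atrial map is unchanged by the ventricular source
  m_a <- solve_eikonal(g, f, data.frame(node = attr(g, "atrial_site"),
                                        t0 = 0))
  expect_equal(m[atr], m_a[atr])
  expect_error(dual_site_initiation(g, f, av_delay = 90), "bounds")
  # removing the insulation leaks the ventricular wavefront
  leaky_lab <- g$labels
  leaky_lab[leaky_lab == "AV-insulation"] <- "ventricular-myo"
  gl <- labeled_grid(g$dims, g$h, leaky_lab, g$fibres[, 1:2])
  attr(gl, "atrial_site") <- attr(g, "atrial_site")
  attr(gl, "ventricular_site") <- attr(g, "ventricular_site")
  fl <- build_velocity_field(gl, cv_f_v = 0.6, cv_f_a = 0.7)
  expect_warning(dual_site_initiation(gl, fl, av_delay = 150), "leak")
})

test_that("total activation time scales with length and speed", {
  g <- strip_grid(81, 3, 0.5)  # 40 mm strip
  f1 <- build_velocity_field(g, cv_f_v = 0.5, k_ft_v = 1)
  f2 <- build_velocity_field(g, cv_f_v = 1.0, k_ft_v = 1)
  m1 <- solve_eikonal(g, f1, data.frame(node = 1, t0 = 0))
  m2 <- solve_eikonal(g, f2, data.frame(node = 1, t0 = 0))
  tat1 <- total_activation_time(m1, "ventricular-myo")
  expect_equal(tat1, 40 / 0.5, tolerance = 0.01)
  expect_equal(total_activation_time(m2, "ventricular-myo"), tat1 / 2,
               tolerance = 1e-6)
  expect_error(total_activation_time(m1, "atrial-myo"), "labels")
  # unreachable nodes are reported with a count
  g2 <- two_slab_geometry(nx = 20, ny = 20, h = 0.5)
  f3 <- build_velocity_field(g2, cv_f_v = 0.6, cv_f_a = 0.6)
  mv <- solve_eikonal(g2, f3,
                      data.frame(node = attr(g2, "ventricular_site"),
                                 t0 = 0))
  expect_error(total_activation_time(mv, "atrial-myo"), "unreachable")
  expect_error(solve_eikonal(g2, f3, data.frame(node = integer(0),
                                                t0 = numeric(0))))
  ins <- which(g2$labels == "AV-insulation")[1]
  expect_error(solve_eikonal(g2, f3, data.frame(node = ins, t0 = 0)),
               "non-conducting")
})
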
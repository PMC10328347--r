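test_that("parameter definitions enforce role-consistent fields", {
  expect_error(param_def("cv", "free", bounds = c(4, 1)), "cv")
  expect_error(param_def("cv", "free", bounds = c(4, 1)), "nverted")
  expect_error(param_def("bcl", "fixed"), "value")
  expect_error(param_def("bcl", "fixed", value = 854, bounds = c(1, 2)))
  expect_error(param_def("x", "free", value = 1), "bounds")
  p <- param_def("AV_delay", "free", bounds = c(100, 200), unit = "ms")
  expect_equal(p$bounds, c(100, 200))
  expect_error(parameter_space(list(p, p)), "duplicate")
})

test_that("the shipped parameter table loads with the study values", {
  path <- system.file("extdata", "parameter_table.yaml",
                      package = "cardioemu")
  sp <- load_parameter_table(path)
  nm <- vapply(sp$params, `[[`, character(1), "name")
  av <- sp$params[[match("AV_delay", nm)]]
  expect_equal(av$bounds, c(100, 200))
  expect_equal(av$role, "free")
  bcl <- sp$params[[match("BCL", nm)]]
  expect_equal(bcl$value, 854)
  expect_equal(unname(sp$fixed["k_ft_v"]), 0.4)
  expect_equal(sp$params[[match("q_ref", nm)]]$value, 82)
  # sampled dimensions: every ranged or HM row, order stable
  roles <- vapply(sp$params, `[[`, character(1), "role")
  expect_equal(sp$D, sum(roles %in% c("free", "hm-constrained")))
  expect_identical(sp$free, nm[roles %in% c("free", "hm-constrained")])
})

test_that("unknown roles and malformed entries are rejected by name", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("parameters:",
               "  - {name: foo, role: wobbly, value: 1}"), bad)
  expect_error(load_parameter_table(bad), "foo")
  expect_error(load_parameter_table("no/such/file.yaml"), "not found")
})

test_that("Latin hypercubes are stratified, in-box and seed-reproducible", {
  for (D in c(2, 5)) {
    sp <- unit_space(D, lower = -2, upper = 3)
    n <- 17
    d <- latin_hypercube(sp, n, seed = 11)
    expect_equal(dim(d), c(n, D))
    U <- scale_to_unit(sp, d)
    # exactly one point per stratum in every dimension
    for (j in seq_len(D))
      expect_identical(sort(findInterval(U[, j], seq(0, 1, by = 1 / n),
                                         rightmost.closed = TRUE)),
                       1:n)
  }
  sp <- unit_space(3)
  expect_identical(unclass(latin_hypercube(sp, 9, seed = 5)),
                   unclass(latin_hypercube(sp, 9, seed = 5)))
  expect_false(identical(unclass(latin_hypercube(sp, 9, seed = 5)),
                         unclass(latin_hypercube(sp, 9, seed = 6))))
  expect_error(latin_hypercube(sp, 0, seed = 1))
})

test_that("unit-box rescaling round-trips to 1e-12", {
  sp <- parameter_space(list(
    param_def("a", "free", bounds = c(-5, 12)),
    param_def("b", "free", bounds = c(0.001, 0.002)),
    param_def("c", "hm-constrained", bounds = c(100, 20000))))
  X <- latin_hypercube(sp, 40, seed = 2)
  back <- scale_from_unit(sp, scale_to_unit(sp, X))
  expect_lt(max(abs(back - unclass(X))), 1e-12)
})

test_that("Saltelli designs have the radial block structure", {
  sp <- unit_space(3, lower = -1, upper = 2)
  d <- saltelli_design(sp, n_base = 4, seed = 9)
  expect_equal(nrow(d), 4 * (3 + 2))
  b <- saltelli_blocks(d)
  for (i in 1:3) {
    expect_identical(b$AB[[i]][, -i], b$A[, -i])
    expect_identical(b$AB[[i]][, i], b$B[, i])
  }
  # blocks recoverable bit-exactly from the flat matrix
  flat <- rbind(b$A, b$B, do.call(rbind, b$AB))
  expect_identical(as.vector(flat), as.vector(unclass(d)))
  d1 <- saltelli_design(unit_space(1), n_base = 2, seed = 1)
  expect_equal(nrow(d1), 6)
  expect_error(saltelli_design(sp, n_base = 1, seed = 1))
})

test_that("space-filling subsampling is greedy maximin", {
  corners <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  # brute-force over all 6 pairs: the diagonal pairs maximise the minimum
  # pairwise distance (sqrt 2)
  for (seed in 1:5) {
    sel <- subsample_space_filling(corners, 2, seed = seed)
    expect_equal(abs(sel[1, 1] - sel[2, 1]), 1)
    expect_equal(abs(sel[1, 2] - sel[2, 2]), 1)
  }
  # beats 100 seeded random subsets on min pairwise distance
  set.seed(42)
  cloud <- matrix(runif(400), 200, 2)
  min_dist <- function(S) min(dist(S))
  sel <- subsample_space_filling(cloud, 12, seed = 3)
  rnd <- replicate(100, min_dist(cloud[sample(200, 12), ]))
  expect_gte(min_dist(sel), max(rnd))
  # identity case: whole cloud, order permuted
  all_sel <- subsample_space_filling(cloud, 200, seed = 1)
  expect_identical(dim(all_sel), dim(cloud))
  expect_equal(sort(all_sel[, 1]), sort(cloud[, 1]))
  expect_error(subsample_space_filling(cloud, 201, seed = 1), "exceeds")
})

test_that("patient-derived constants recompute the study configuration", {
  expect_equal(derive_qref(70, 854), 70 / 0.854)
  expect_equal(derive_hr(854), 60000 / 854)
  r <- sqrt(336.7 / pi)
  expect_equal(tube_wall_area(336.7, 2), pi * ((r + 2)^2 - r^2))
})
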
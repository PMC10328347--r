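# shared fixtures and independent oracles

# a unit-box parameter space of dimension D
unit_space <- function(D, lower = 0, upper = 1) {
  parameter_space(lapply(seq_len(D), function(i)
    param_def(paste0("x", i), "free", bounds = c(lower, upper))))
}

# smooth 3-D test function used for emulator accuracy checks
smooth3 <- function(X) sin(2 * X[, 1]) + X[, 2]^2 + 0.5 * X[, 3] * X[, 1]

# Ishigami function on [-pi, pi]^3 and its closed-form total effects
ishigami <- function(X, a = 7, b = 0.1)
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])

ishigami_total_effects <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- 8 * b^2 * pi^8 / 225
  v <- v1 + v2 + v13
  c((v1 + v13) / v, v2 / v, v13 / v)
}

# brute-force double-loop Monte-Carlo total effects:
# S_Ti = E_x~i[ Var_xi( f | x~i ) ] / Var(f)
brute_force_total_effects <- function(f, D, n_outer, n_inner, seed) {
  set.seed(seed)
  Xo <- matrix(stats::runif(n_outer * D), n_outer, D)
  st <- numeric(D)
  all_y <- f(matrix(stats::runif(4000 * D), 4000, D))
  vtot <- stats::var(all_y)
  for (i in seq_len(D)) {
    cond_var <- vapply(seq_len(n_outer), function(j) {
      X <- Xo[rep(j, n_inner), , drop = FALSE]
      X[, i] <- stats::runif(n_inner)
      stats::var(f(X))
    }, numeric(1))
    st[i] <- mean(cond_var) / vtot
  }
  st
}

# graph-Dijkstra activation times with the same anisotropic metric
# (8-neighbour edges): an upper bound on the continuous solution that the
# grid solver must not exceed
dijkstra_times <- function(grid, field, src_node, t0 = 0) {
  d <- grid$dims
  n <- grid$n
  coords <- node_coords(grid)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  tt <- rep(Inf, n)
  tt[src_node] <- t0
  done <- rep(FALSE, n)
  edge_w <- function(from, to) {
    e <- coords[to, 1:2] - coords[from, 1:2]
    fv <- grid$fibres[to, 1:2]
    ef <- sum(e * fv)
    q <- ef^2 / field$cf[to]^2 + (sum(e^2) - ef^2) / field$ct[to]^2
    sqrt(q)
  }
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, tt))
    if (!is.finite(tt[u])) break
    done[u] <- TRUE
    ui <- (u - 1) %% d[1] + 1
    uj <- (u - 1) %/% d[1] + 1
    for (k in seq_len(nrow(offs))) {
      vi <- ui + offs[k, 1]; vj <- uj + offs[k, 2]
      if (vi < 1 || vi > d[1] || vj < 1 || vj > d[2]) next
      v <- vi + d[1] * (vj - 1)
      if (done[v] || !field$conducting[v]) next
      w <- tt[u] + edge_w(u, v)
      if (w < tt[v]) tt[v] <- w
    }
  }
  tt
}

# steady state of the crossbridge chain at a constant permissive fraction p
# (flux balance of the linear chain U <-> W <-> S)
crossbridge_steady_state <- function(p, lp) {
  ustar <- 1 - lp$r_s * (1 + lp$r_w)
  a1 <- lp$kb * lp$nu * p
  d1 <- lp$kb * lp$nu * ustar / (lp$r_w * lp$r_s)
  a2 <- lp$kb * lp$mu
  d2 <- lp$kb * lp$mu * lp$r_w
  # S = (a2/d2) W, W = (a1/d1) U, U + W + S = 1
  wu <- a1 / d1
  sw <- a2 / d2
  u <- 1 / (1 + wu + wu * sw)
  c(U = u, W = wu * u, S = wu * sw * u)
}

# toy 1-D history-matching problem: f(x) = x^2, target 0.25
toy_hm_space <- function() parameter_space(param_def("x", "free",
                                                     bounds = c(-1, 1)))
toy_hm_sim <- function(X) matrix(X[, 1]^2, ncol = 1,
                                 dimnames = list(NULL, "y"))

# memoised default tension drivers (shared by circulation tests)
cached_drivers <- local({
  cache <- NULL
  function(bcl = 854) {
    if (is.null(cache)) cache <<- default_tension_drivers(bcl)
    cache
  }
})
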
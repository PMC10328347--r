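#' History-matching targets
#'
#' A target per output: the measured (or literature) value \eqn{\mu_i} and
#' its standard deviation \eqn{\sigma_i}, in the output's units.
#'
#' @param output character vector of output names.
#' @param mu measured target values.
#' @param sigma measurement standard deviations (> 0).
#' @return data.frame of class \code{"hm_targets"}.
#' @export
hm_targets <- function(output, mu, sigma) {
  stopifnot(length(output) == length(mu), length(mu) == length(sigma))
  if (any(sigma <= 0)) stop("target sigma must be > 0")
  if (anyDuplicated(output)) stop("duplicate target output names")
  structure(data.frame(output = as.character(output), mu = as.numeric(mu),
                       sigma = as.numeric(sigma),
                       stringsAsFactors = FALSE),
            class = c("hm_targets", "data.frame"))
}

#' Implausibility of emulated outputs against targets
#'
#' For each point, the per-output implausibility is
#' \deqn{I_i^2(x) = \frac{(E[f_i(x)|D] - \mu_i)^2}
#'                       {\sigma^2[f_i(x)|D] + \sigma_i^2},}
#' combining emulator predictive variance and measurement variance; the
#' reported implausibility is the maximum over outputs.
#'
#' @param mean matrix of posterior means (points x outputs), columns named
#'   by output.
#' @param sd matrix of posterior standard deviations, same shape.
#' @param targets \code{\link{hm_targets}}; every predicted output must
#'   have a target.
#' @return numeric vector of per-point implausibilities.
#' @export
implausibility <- function(mean, sd, targets) {
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  stopifnot(identical(dim(mean), dim(sd)))
  nm <- colnames(mean)
  if (is.null(nm)) {
    if (ncol(mean) != nrow(targets))
      stop("unnamed prediction columns and target count mismatch")
    nm <- targets$output
    colnames(mean) <- colnames(sd) <- nm
  }
  missing <- setdiff(nm, targets$output)
  if (length(missing))
    stop("no target for predicted output(s): ",
         paste(missing, collapse = ", "))
  tg <- targets[match(nm, targets$output), ]
  I2 <- matrix(NA_real_, nrow(mean), ncol(mean))
  for (j in seq_len(ncol(mean)))
    I2[, j] <- (mean[, j] - tg$mu[j])^2 / (sd[, j]^2 + tg$sigma[j]^2)
  sqrt(apply(I2, 1, max))
}

# predict a named emulator list over X and return the per-point max
# implausibility
implausibility_of <- function(models, X, targets) {
  preds <- lapply(models, predict, newdata = X)
  mean <- vapply(preds, `[[`, numeric(nrow(as_design_matrix(X))), "mean")
  sd <- vapply(preds, `[[`, numeric(nrow(as_design_matrix(X))), "sd")
  if (is.null(dim(mean))) { mean <- t(mean); sd <- t(sd) }
  colnames(mean) <- colnames(sd) <- names(models)
  implausibility(mean, sd, targets)
}

#' Run one history-matching wave
#'
#' A wave trains per-output emulators on the cumulative successful
#' simulations, evaluates them on a fresh Latin hypercube test cloud,
#' computes the implausibility of every test point against the targets,
#' splits the cloud into plausible and implausible regions and selects the
#' next batch of simulation points from the plausible region by space-filling
#' subsampling (the \code{from_implausible} flag flips the selection region).
#' The returned state carries the proposed points already simulated, so
#' successive calls iterate the wave loop.
#'
#' @param prev a \code{\link{parameter_space}} (first wave) or the
#'   \code{"hm_wave"} state returned by the previous call.
#' @param simulator function mapping a design matrix to a matrix of outputs
#'   (rows = design rows, columns named by output); rows may be all-NA to
#'   signal failed runs.
#' @param targets \code{\link{hm_targets}}.
#' @param I_th implausibility threshold for this wave (default 3, the
#'   3-sigma rule).
#' @param n_test test cloud size (default 100000).
#' @param n_simul number of new simulation points proposed per wave.
#' @param seed integer seed.
#' @param from_implausible select new simulation points from the implausible
#'   region instead (non-standard; off by default).
#' @param ... further arguments passed to \code{\link{gpe}}.
#' @return object of class \code{"hm_wave"}: training data, emulators, test
#'   cloud, implausibilities, plausible mask, diagnostics, and the next
#'   training set proposal.
#' @export
hm_wave <- function(prev, simulator, targets, I_th = 3, n_test = 100000,
                    n_simul, seed = 1, from_implausible = FALSE, ...) {
  if (inherits(prev, "parameter_space")) {
    space <- prev
    wave <- 1L
    if (missing(n_simul)) n_simul <- 10L * space$D
    if (n_simul < space$D + 2) stop("n_simul must be at least D + 2")
    X_new <- latin_hypercube(space, n_simul, seed)
    X <- unclass(X_new); Y <- NULL
  } else if (inherits(prev, "hm_wave")) {
    space <- prev$space
    wave <- prev$wave + 1L
    if (missing(n_simul)) n_simul <- nrow(prev$proposal)
    if (prev$exhausted)
      stop("previous wave exhausted the plausible region; nothing to refine")
    X <- rbind(prev$X, unclass(prev$proposal))
    Y <- prev$Y
  } else stop("prev must be a parameter_space or an hm_wave state")

  # simulate the newly proposed points
  new_rows <- if (is.null(Y)) seq_len(nrow(X)) else
    seq(nrow(Y) + 1L, nrow(X))
  Y_new <- simulator(X[new_rows, , drop = FALSE])
  if (is.null(dim(Y_new))) Y_new <- matrix(Y_new, ncol = 1)
  if (is.null(colnames(Y_new)))
    colnames(Y_new) <- targets$output[seq_len(ncol(Y_new))]
  Y <- rbind(Y, Y_new)
  success <- apply(is.finite(Y), 1, all)
  if (mean(!success[new_rows]) > 0.5)
    warning(sprintf("wave %d: %.0f%% of new simulator runs failed", wave,
                    100 * mean(!success[new_rows])))
  if (sum(success) < space$D + 2)
    stop("not enough successful simulations to train emulators")

  # per-output emulators on the cumulative successful runs
  Xtr <- X[success, , drop = FALSE]
  attr(Xtr, "space") <- space
  models <- lapply(stats::setNames(colnames(Y), colnames(Y)), function(o)
    gpe(Xtr, Y[success, o], seed = seed, ...))

  # fresh test cloud and implausibility split
  cloud <- latin_hypercube(space, n_test, seed + 7919L)
  I <- implausibility_of(models, unclass(cloud), targets)
  plausible <- I <= I_th

  # per-output predictive-variance ratio against target variance
  sdm <- vapply(models, function(m) predict(m, unclass(cloud))$sd,
                numeric(n_test))
  vr <- sweep(sdm^2, 2,
              targets$sigma[match(colnames(Y), targets$output)]^2, "/")
  v_ratio <- apply(vr, 1, max)

  exhausted <- !any(plausible)
  proposal <- if (exhausted) {
    unclass(cloud)[integer(0), , drop = FALSE]
  } else {
    pool <- unclass(cloud)[xor(plausible, from_implausible), , drop = FALSE]
    if (nrow(pool) == 0) pool <- unclass(cloud)
    subsample_space_filling(pool, min(n_simul, nrow(pool)), seed + 13L,
                            space = space)
  }

  state <- structure(list(
    wave = wave, space = space, X = X, Y = Y, success = success,
    models = models, cloud = cloud, I = I, plausible = plausible,
    v_ratio = v_ratio, I_th = I_th, proposal = proposal,
    exhausted = exhausted, seed = seed), class = "hm_wave")
  state$diagnostics <- wave_diagnostics(state)
  state
}

#' Diagnostics of a history-matching wave
#'
#' Summarises the test cloud of a wave: the percentage of non-implausible
#' points, the mean and maximum implausibility, and the mean and maximum
#' ratio of emulator predictive variance to the target variance
#' (\eqn{V_{ratio}}), which measures how uncertain the emulators are
#' relative to the uncertainty of the data being matched.
#'
#' @param state an \code{"hm_wave"} state.
#' @return list of class \code{"hm_diagnostics"}.
#' @export
wave_diagnostics <- function(state) {
  stopifnot(inherits(state, "hm_wave"))
  structure(list(wave = state$wave,
                 percent_plausible = 100 * mean(state$plausible),
                 mean_I = mean(state$I), max_I = max(state$I),
                 mean_v_ratio = mean(state$v_ratio),
                 max_v_ratio = max(state$v_ratio),
                 n_train = sum(state$success),
                 n_test = length(state$I)),
            class = "hm_diagnostics")
}

#' @export
print.hm_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Wave %d: %.2f%% non-implausible | I mean %.3g max %.3g | V_ratio mean %.3g max %.3g | %d training runs, %d test points\n",
    x$wave, x$percent_plausible, x$mean_I, x$max_I, x$mean_v_ratio,
    x$max_v_ratio, x$n_train, x$n_test))
  invisible(x)
}

#' @export
print.hm_wave <- function(x, ...) {
  cat(sprintf("History-matching wave %d (I_th = %g)%s\n", x$wave, x$I_th,
              if (x$exhausted) " [plausible region exhausted]" else ""))
  print(x$diagnostics)
  invisible(x)
}

#' Combine plausible regions over disjoint parameter blocks
#'
#' Sub-model history matching yields plausible clouds over disjoint blocks
#' of the joint parameter space. Joint samples are formed by independently
#' shuffling the rows of each cloud (seeded) and concatenating them
#' column-wise, truncated to the smallest cloud, which preserves each
#' block's marginal distribution while pairing blocks at random.
#'
#' @param clouds list of design matrices over pairwise-disjoint parameter
#'   blocks (columns named).
#' @param extra_lhs optional further design (e.g. a Latin hypercube over the
#'   unconstrained parameters) combined the same way; may have zero rows to
#'   be ignored.
#' @param seed integer seed for the shuffles.
#' @return matrix of joint samples over the union of the blocks.
#' @export
intersect_regions <- function(clouds, extra_lhs = NULL, seed = 1) {
  if (!is.null(extra_lhs) && nrow(extra_lhs) > 0)
    clouds <- c(clouds, list(extra_lhs))
  clouds <- lapply(clouds, as_design_matrix)
  nms <- unlist(lapply(clouds, colnames))
  if (anyDuplicated(nms))
    stop("parameter blocks overlap: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  n <- min(vapply(clouds, nrow, integer(1)))
  shuffled <- with_seed(seed, lapply(clouds, function(cl)
    cl[sample.int(nrow(cl))[seq_len(n)], , drop = FALSE]))
  do.call(cbind, shuffled)
}

#' Validate an implausibility-threshold schedule
#'
#' Wave thresholds must be non-increasing; the final threshold defaults to
#' 3 (the 3-sigma rule). A valid schedule ending above 3 is accepted with a
#' warning and extended by a final 3.
#'
#' @param schedule numeric vector of per-wave thresholds.
#' @param final required final threshold (default 3).
#' @return the validated (possibly extended) schedule.
#' @export
final_threshold_check <- function(schedule, final = 3) {
  stopifnot(length(schedule) >= 1, all(is.finite(schedule)))
  if (any(diff(schedule) > 0))
    stop("implausibility schedule must be non-increasing")
  if (utils::tail(schedule, 1) > final) {
    warning(sprintf("schedule ends at %g > %g; appending a final %g wave",
                    utils::tail(schedule, 1), final, final))
    schedule <- c(schedule, final)
  }
  schedule
}
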
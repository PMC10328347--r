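#' Sobol total effects via Saltelli sampling and the Jansen estimator
#'
#' Computes variance-based total-effect indices \eqn{S_{T,i}} for every
#' parameter and output. A Saltelli design with blocks A, B and AB_i is
#' evaluated either through fitted emulators or through an exact function;
#' the total effect uses Jansen's estimator
#' \deqn{S_{T,i} = \frac{\frac{1}{2N}\sum_j (f(A_j) - f(AB_{i,j}))^2}
#'                     {\mathrm{Var}[f]},}
#' with the output variance estimated from the A and B blocks. When
#' emulators are supplied, the estimator is averaged over \code{n_draws}
#' posterior draws (independent per-point draws, the scalable scheme for
#' large designs) and the across-draw standard deviation is reported, so
#' emulator uncertainty propagates into the indices. First-order indices
#' are computed alongside with the Jansen form
#' \eqn{S_i = 1 - \frac{1}{2N \mathrm{Var}[f]}\sum_j (f(B_j) - f(AB_{i,j}))^2}.
#'
#' @param models named list of fitted \code{\link{gpe}} objects (one per
#'   output, all sharing the space), or a single function mapping a design
#'   matrix to a numeric vector or to a matrix with one column per output.
#' @param space the \code{\link{parameter_space}} sampled.
#' @param n_base Saltelli base sample size.
#' @param n_draws posterior draws per output (ignored for an exact
#'   function).
#' @param seed integer seed (design + posterior draws).
#' @param design optional pre-built Saltelli design to reuse.
#' @return object of class \code{"sobol_result"} with \code{total_effects}
#'   and \code{total_effects_sd} (D x M), \code{first_order},
#'   \code{constant_outputs} and the sampling settings.
#' @export
sobol_total_effects <- function(models, space, n_base, n_draws = 1000,
                                seed = 1, design = NULL) {
  stopifnot(inherits(space, "parameter_space"))
  D <- space$D
  if (is.null(design)) design <- saltelli_design(space, n_base, seed)
  n_base <- attr(design, "n_base")
  exact <- is.function(models)
  if (!exact) {
    if (inherits(models, "gpe")) models <- list(output = models)
    stopifnot(all(vapply(models, inherits, logical(1), "gpe")))
    out_names <- names(models)
    if (is.null(out_names)) out_names <- paste0("y", seq_along(models))
  }

  Xall <- unclass(design)
  if (exact) {
    Y <- models(Xall)
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
    out_names <- colnames(Y)
    if (is.null(out_names)) out_names <- paste0("y", seq_len(ncol(Y)))
    n_draws <- 1L
  }
  M <- length(out_names)

  ST <- ST_sd <- S1 <- matrix(NA_real_, D, M,
                              dimnames = list(space$free, out_names))
  const <- logical(M); names(const) <- out_names
  iA <- seq_len(n_base); iB <- n_base + iA
  for (m in seq_len(M)) {
    if (exact) {
      draws <- matrix(Y[, m], ncol = 1)
    } else {
      p <- predict(models[[m]], Xall)
      Z <- with_seed(seed + m, matrix(stats::rnorm(nrow(Xall) * n_draws),
                                      nrow(Xall), n_draws))
      draws <- p$mean + p$sd * Z
    }
    st_d <- matrix(NA_real_, D, ncol(draws))
    s1_d <- matrix(NA_real_, D, ncol(draws))
    for (d in seq_len(ncol(draws))) {
      f <- draws[, d]
      v <- stats::var(c(f[iA], f[iB]))
      if (!is.finite(v) || v < 1e-300) {
        st_d[, d] <- 0; s1_d[, d] <- 0
        const[m] <- TRUE
        next
      }
      for (i in seq_len(D)) {
        fABi <- f[(i + 1L) * n_base + iA]
        st_d[i, d] <- mean((f[iA] - fABi)^2) / (2 * v)
        s1_d[i, d] <- 1 - mean((f[iB] - fABi)^2) / (2 * v)
      }
    }
    ST[, m] <- rowMeans(st_d)
    ST_sd[, m] <- if (ncol(st_d) > 1) apply(st_d, 1, stats::sd) else 0
    S1[, m] <- rowMeans(s1_d)
  }
  if (any(const))
    warning("constant output(s), total effects reported as 0: ",
            paste(out_names[const], collapse = ", "))
  structure(list(total_effects = ST, total_effects_sd = ST_sd,
                 first_order = S1, constant_outputs = const,
                 n_base = n_base, n_draws = n_draws, seed = seed,
                 space = space),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, digits = 3, ...) {
  cat(sprintf("Sobol total effects: %d parameters x %d outputs (n_base = %d, %d posterior draw%s)\n",
              nrow(x$total_effects), ncol(x$total_effects), x$n_base,
              x$n_draws, if (x$n_draws == 1) "" else "s"))
  print(round(x$total_effects, digits))
  invisible(x)
}

#' Heatmap-ready normalisation of a total-effect matrix
#'
#' Scales each output column of the total-effect matrix to [0, 1] (column
#' maximum = 1), clipping small negative Monte-Carlo estimates to 0 for
#' display. The stored raw results are left untouched.
#'
#' @param result a \code{\link{sobol_total_effects}} result or a D x M
#'   matrix.
#' @return D x M matrix with per-column maximum 1 (all-zero columns stay 0).
#' @export
normalize_effects <- function(result) {
  S <- if (inherits(result, "sobol_result")) result$total_effects else result
  S <- pmax(S, 0)
  mx <- apply(S, 2, max)
  mx[mx == 0] <- 1
  sweep(S, 2, mx, "/")
}

#' @export
plot.sobol_result <- function(x, ...) {
  S <- normalize_effects(x)
  graphics::image(seq_len(ncol(S)), seq_len(nrow(S)), t(S[rev(seq_len(nrow(S))), , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, seq_len(ncol(S)), colnames(S), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(S)), rev(rownames(S)), las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Rank parameters and retain the leading set
#'
#' Scores each parameter by its maximum total effect across outputs,
#' normalises the scores to sum to 1 (a share of the explained output
#' variation) and retains the shortest prefix of the descending ranking
#' whose cumulative share reaches the threshold. Ties are broken by the
#' stable parameter order of the space.
#'
#' @param result a \code{\link{sobol_total_effects}} result.
#' @param threshold cumulative share to retain (default 0.90).
#' @return object of class \code{"gsa_ranking"} with \code{order} (ranked
#'   names), \code{normalized_max} (shares, ranked order), \code{retained}
#'   (names) and \code{cumulative}.
#' @export
rank_and_retain <- function(result, threshold = 0.90) {
  S <- pmax(result$total_effects, 0)
  score <- apply(S, 1, max)
  if (all(score == 0)) stop("all total effects are zero; nothing to rank")
  ord <- order(-score)           # radix sort: stable for ties
  share <- score[ord] / sum(score)
  cum <- cumsum(share)
  n_keep <- which(cum >= threshold - 1e-12)[1]
  structure(list(order = rownames(S)[ord],
                 normalized_max = stats::setNames(share, rownames(S)[ord]),
                 cumulative = stats::setNames(cum, rownames(S)[ord]),
                 retained = rownames(S)[ord][seq_len(n_keep)],
                 threshold = threshold),
            class = "gsa_ranking")
}

#' @export
print.gsa_ranking <- function(x, ...) {
  cat(sprintf("Parameter ranking (retain >= %.0f%% cumulative share): %d of %d retained\n",
              100 * x$threshold, length(x$retained), length(x$order)))
  df <- data.frame(parameter = x$order,
                   share = round(unname(x$normalized_max), 4),
                   cumulative = round(unname(x$cumulative), 4),
                   retained = x$order %in% x$retained)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Signed total effects
#'
#' Multiplies each total effect by the sign of the corresponding linear-mean
#' regression coefficient of the output's emulator, indicating whether the
#' parameter pushes the output up or down over its range. A zero
#' coefficient keeps sign 0.
#'
#' @param result a \code{\link{sobol_total_effects}} result.
#' @param models the named emulator list the result was computed from.
#' @return D x M signed matrix.
#' @export
signed_effects <- function(result, models) {
  if (inherits(models, "gpe")) models <- list(models)
  S <- result$total_effects
  B <- vapply(models, function(m) coef(m)[-1], numeric(nrow(S)))
  if (!is.null(names(models))) colnames(B) <- names(models)
  S * sign(B[rownames(S), colnames(S), drop = FALSE])
}

## ---- plausibility screening of GSA samples ----------------------------

#' Screen design rows through sub-model emulator constraints
#'
#' Each constraint names a block of design columns, carries the emulators
#' trained on that sub-model and the targets its outputs must match. A row
#' passes when every constraint block's implausibility is at most
#' \code{I_th}. With no constraints every row passes.
#'
#' @param design design matrix whose columns include every constrained
#'   parameter.
#' @param constraints list of constraints, each a list with elements
#'   \code{models} (named \code{\link{gpe}} list), \code{targets}
#'   (see \code{\link{hm_targets}}) and \code{params} (character vector of
#'   design columns the emulators consume, in training order).
#' @param I_th implausibility threshold (default 3).
#' @return logical mask over the design rows.
#' @export
screen_samples <- function(design, constraints, I_th = 3) {
  X <- as_design_matrix(design)
  mask <- rep(TRUE, nrow(X))
  for (ct in constraints) {
    sub <- X[, ct$params, drop = FALSE]
    I <- implausibility_of(ct$models, sub, ct$targets)
    mask <- mask & (I <= I_th)
  }
  mask
}

#' Grow a plausible base sequence for a screened sensitivity analysis
#'
#' Generates a Latin hypercube base sequence over the space, screens it with
#' \code{\link{screen_samples}}, and enlarges the sequence until more than
#' \code{n_required} plausible rows are found.
#'
#' @param space the \code{\link{parameter_space}} to sample.
#' @param constraints constraint list as in \code{\link{screen_samples}};
#'   constrained blocks must cover disjoint column sets.
#' @param I_th implausibility threshold.
#' @param n_required number of plausible rows needed (default 2000).
#' @param n_base initial base sequence size (default 2000).
#' @param max_iter maximum number of enlargements.
#' @param seed integer seed.
#' @return design matrix of plausible rows (> \code{n_required} of them).
#' @export
plausible_base_sequence <- function(space, constraints, I_th = 3,
                                    n_required = 2000, n_base = 2000,
                                    max_iter = 10, seed = 1) {
  blocks <- lapply(constraints, `[[`, "params")
  all_p <- unlist(blocks)
  if (anyDuplicated(all_p))
    stop("constraint blocks overlap: ",
         paste(unique(all_p[duplicated(all_p)]), collapse = ", "))
  n <- n_base
  for (it in seq_len(max_iter)) {
    X <- latin_hypercube(space, n, seed + it - 1L)
    mask <- screen_samples(X, constraints, I_th)
    if (sum(mask) > n_required) {
      out <- unclass(X)[mask, , drop = FALSE]
      return(new_design(out, space, "cloud", seed))
    }
    if (it == max_iter && mean(mask) < 0.001)
      stop(sprintf(
        "plausible fraction %.4f%% after %d enlargements (n = %d): targets unreachable",
        100 * mean(mask), max_iter, n))
    n <- n * 2L
  }
  stop(sprintf("fewer than %d plausible rows after %d enlargements",
               n_required, max_iter))
}
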
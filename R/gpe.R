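#' Fit a Gaussian-process emulator
#'
#' Fits a per-output Gaussian-process emulator with a linear prior mean
#' \eqn{E[f(x)] = \beta_0 + \sum_i \beta_i x_i} and a stationary kernel
#' (exponentiated quadratic by default, Matern-5/2 as an alternative) with
#' per-dimension lengthscales, a signal variance and an optional nugget.
#' Inputs are rescaled to the unit box and the output is centred and scaled
#' by its training mean and standard deviation before fitting. Kernel
#' hyperparameters maximise the marginal likelihood with the trend
#' coefficients profiled out by generalised least squares; the optimiser is
#' L-BFGS-B with seeded multi-restarts.
#'
#' @param X training inputs, \code{n x D} matrix (rows = simulator runs). A
#'   design matrix carrying a parameter space provides the unit-box scaling;
#'   otherwise the training column ranges are used.
#' @param y training outputs, length-\code{n} numeric; must be finite.
#' @param kernel \code{"exp_quadratic"} or \code{"matern52"}.
#' @param nugget \code{"fit"} (bounded above by \code{nugget_max} times the
#'   output variance) or \code{"fixed"}.
#' @param nugget_value fixed nugget variance relative to the (unit) scaled
#'   output variance, used when \code{nugget = "fixed"}; 0 means
#'   interpolation up to jitter.
#' @param nugget_max upper bound on the fitted relative nugget.
#' @param n_restarts number of random optimiser restarts.
#' @param seed integer seed for the restarts.
#' @param jitter diagonal jitter for numerical stability.
#' @return an object of class \code{"gpe"}.
#' @seealso \code{\link{predict.gpe}}, \code{\link{simulate.gpe}},
#'   \code{\link{cross_validate}}
#' @export
gpe <- function(X, y, kernel = c("exp_quadratic", "matern52"),
                nugget = c("fit", "fixed"), nugget_value = 0,
                nugget_max = 1e-4, n_restarts = 5, seed = 1,
                jitter = 1e-8) {
  kernel <- match.arg(kernel)
  nugget <- match.arg(nugget)
  space <- attr(X, "space")
  X <- as_design_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); D <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (!all(is.finite(y))) stop("non-finite outputs in y")
  if (!all(is.finite(X))) stop("non-finite inputs in X")
  if (n < D + 2) stop(sprintf("need at least D + 2 = %d training rows, got %d",
                              D + 2, n))

  # unit-box input scaling: space bounds if available, else training ranges
  if (!is.null(space)) {
    lo <- space$bounds[, 1]; hi <- space$bounds[, 2]
  } else {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  }
  rng <- hi - lo
  rng[rng <= 0] <- 1
  Xs <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")

  y_mean <- mean(y); y_sd <- stats::sd(y)
  degenerate <- !is.finite(y_sd) || y_sd < 1e-12 * max(1, abs(y_mean))
  obj <- structure(list(kernel = kernel, X = X, Xs = Xs, y = y,
                        x_lo = lo, x_rng = rng,
                        y_mean = y_mean, y_sd = if (degenerate) 1 else y_sd,
                        degenerate = degenerate, jitter = jitter,
                        space = space),
                   class = "gpe")
  if (degenerate) {
    warning("constant training output: fitted with zero signal variance")
    obj$theta <- c(log_ell = rep(0, D), log_sf2 = log(1e-12),
                   log_sn2 = log(1e-12))
    obj$beta <- c(y_mean, rep(0, D))
    obj <- gpe_precompute(obj)
    return(obj)
  }
  ys <- (y - y_mean) / y_sd

  # optimise log lengthscales (unit box; bounded by twice the box diameter,
  # the usual kriging cap) and the log nugget-to-signal ratio; the signal
  # variance and the trend are profiled out analytically
  fit_g <- nugget == "fit"
  lower <- c(rep(log(0.03), D), log(1e-9))
  upper <- c(rep(log(2), D),
             if (fit_g) log(nugget_max) else log(1e-9))
  fixed_g <- if (fit_g) NULL else max(nugget_value, 0)

  nll <- function(theta) gpe_nll(theta, Xs, ys, kernel, jitter, fixed_g,
                                 grad = FALSE)
  grr <- function(theta) gpe_nll(theta, Xs, ys, kernel, jitter, fixed_g,
                                 grad = TRUE)

  starts <- with_seed(seed, {
    s0 <- c(rep(log(0.5), D), log(1e-6))
    more <- replicate(max(0, n_restarts - 1),
                      c(log(stats::runif(D, 0.1, 1.5)),
                        log(stats::runif(1, 1e-8, 1e-5))),
                      simplify = FALSE)
    c(list(s0), more)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper), fn = nll,
                   gr = if (kernel == "exp_quadratic") grr else NULL,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 150)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("hyperparameter optimisation failed at every restart")

  # recover the profiled signal variance at the optimum
  par <- best$par
  g <- if (fit_g) exp(par[D + 1L]) else fixed_g
  prof <- gpe_profile(par[seq_len(D)], g, Xs, ys, kernel, jitter)
  obj$theta <- c(par[seq_len(D)], log(max(prof$sf2, 1e-300)),
                 log(max(prof$sf2 * g, 1e-300)))
  names(obj$theta) <- c(paste0("log_ell_", colnames(X)), "log_sf2",
                        "log_sn2")
  obj$nll <- best$value
  gpe_precompute(obj)
}

# kernel matrix on unit-box inputs (no noise term)
gpe_kernel <- function(A, B, theta, kernel) {
  D <- ncol(A)
  ell <- exp(theta[seq_len(D)]); sf2 <- exp(theta[D + 1L])
  As <- sweep(A, 2, ell, "/"); Bs <- sweep(B, 2, ell, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  d2[d2 < 0] <- 0
  if (kernel == "exp_quadratic") {
    sf2 * exp(-0.5 * d2)
  } else {
    r <- sqrt(5 * d2)
    sf2 * (1 + r + r^2 / 3) * exp(-r)
  }
}

# concentrated negative log marginal likelihood: the trend is profiled by
# generalised least squares and the signal variance by its closed-form
# estimate sf2 = r' C^-1 r / n given the correlation matrix C (with nugget
# ratio g), which removes the scale degeneracy of the full likelihood on
# noise-free data. The gradient (exponentiated quadratic kernel) uses the
# envelope theorem for both profiled quantities.
gpe_nll <- function(theta, Xs, ys, kernel, jitter, fixed_g, grad = FALSE) {
  n <- nrow(Xs); D <- ncol(Xs)
  g <- if (is.null(fixed_g)) exp(theta[D + 1L]) else fixed_g
  th_corr <- c(theta[seq_len(D)], 0)     # unit signal variance
  C0 <- gpe_kernel(Xs, Xs, th_corr, kernel)
  Cg <- C0 + diag(g + jitter, n)
  L <- tryCatch(chol(Cg), error = function(e) NULL)
  if (is.null(L)) {
    if (grad) return(rep(0, length(theta)))
    return(1e10)
  }
  H <- cbind(1, Xs)
  Ci_y <- backsolve(L, forwardsolve(t(L), ys))
  Ci_H <- backsolve(L, forwardsolve(t(L), H))
  A <- crossprod(H, Ci_H)
  beta <- tryCatch(solve(A, crossprod(H, Ci_y)), error = function(e) NULL)
  if (is.null(beta)) {
    if (grad) return(rep(0, length(theta)))
    return(1e10)
  }
  r <- as.numeric(ys - H %*% beta)
  alpha <- backsolve(L, forwardsolve(t(L), r))
  rCr <- sum(r * alpha)
  if (rCr <= 0) {
    if (grad) return(rep(0, length(theta)))
    return(1e10)
  }
  if (!grad)
    return(0.5 * n * log(rCr / n) + sum(log(diag(L))))
  Ci <- chol2inv(L)
  gr <- numeric(length(theta))
  quad <- function(dC) 0.5 * (sum(Ci * dC) - n * sum(alpha * (dC %*% alpha)) / rCr)
  for (i in seq_len(D)) {
    d <- outer(Xs[, i], Xs[, i], "-") / exp(theta[i])
    gr[i] <- quad(C0 * d^2)
  }
  if (is.null(fixed_g))
    gr[D + 1L] <- 0.5 * g * (sum(diag(Ci)) - n * sum(alpha^2) / rCr)
  gr
}

# profiled signal variance at given lengthscales and nugget ratio
gpe_profile <- function(log_ell, g, Xs, ys, kernel, jitter) {
  n <- nrow(Xs)
  C0 <- gpe_kernel(Xs, Xs, c(log_ell, 0), kernel)
  L <- chol(C0 + diag(g + jitter, n))
  H <- cbind(1, Xs)
  Ci_y <- backsolve(L, forwardsolve(t(L), ys))
  Ci_H <- backsolve(L, forwardsolve(t(L), H))
  A <- crossprod(H, Ci_H)
  beta <- solve(A, crossprod(H, Ci_y))
  r <- as.numeric(ys - H %*% beta)
  alpha <- backsolve(L, forwardsolve(t(L), r))
  list(sf2 = sum(r * alpha) / n, beta = as.numeric(beta))
}

# cache the Cholesky and GLS quantities on the fitted object
gpe_precompute <- function(obj) {
  n <- nrow(obj$Xs); D <- ncol(obj$Xs)
  ys <- (obj$y - obj$y_mean) / obj$y_sd
  sf2 <- exp(obj$theta[D + 1L])
  sn2 <- exp(obj$theta[D + 2L])
  # final factorisation uses the smallest jitter the Cholesky tolerates,
  # so noise-free training data is interpolated as tightly as possible
  K0 <- gpe_kernel(obj$Xs, obj$Xs, obj$theta, obj$kernel)
  L <- NULL
  jit <- obj$jitter * max(sf2, 1) * 1e-4
  while (is.null(L)) {
    L <- tryCatch(chol(K0 + diag(sn2 + jit, n)), error = function(e) NULL)
    if (is.null(L)) jit <- jit * 10
    if (jit > 1e6) stop("kernel matrix is numerically singular")
  }
  K <- K0 + diag(sn2 + jit, n)
  H <- cbind(1, obj$Xs)
  Kinv_H <- backsolve(L, forwardsolve(t(L), H))
  A <- crossprod(H, Kinv_H)
  if (obj$degenerate) {
    beta <- c(0, rep(0, D))
  } else {
    beta <- as.numeric(solve(A, crossprod(H, backsolve(L, forwardsolve(t(L), ys)))))
  }
  r <- ys - as.numeric(H %*% beta)
  obj$L <- L
  obj$alpha <- backsolve(L, forwardsolve(t(L), r))
  obj$Kinv_H <- Kinv_H
  obj$Ainv <- solve(A)
  obj$beta_scaled <- beta
  # beta on the native output scale / unit-box input scale
  obj$beta <- c(obj$y_mean + obj$y_sd * beta[1], obj$y_sd * beta[-1])
  names(obj$beta) <- c("(Intercept)", colnames(obj$X))
  obj
}

#' Posterior prediction from a Gaussian-process emulator
#'
#' Returns the posterior mean \eqn{E[f(x)|D]} and standard deviation
#' \eqn{\sigma[f(x)|D]} at new points. The variance includes the
#' generalised-least-squares contribution of the estimated trend.
#' Extrapolation outside the training box is allowed; points outside are
#' flagged in the \code{extrapolated} column.
#'
#' @param object fitted \code{\link{gpe}}.
#' @param newdata matrix of prediction points in native units (columns as
#'   the training inputs). Zero rows give an empty prediction.
#' @param ... unused.
#' @return data.frame with columns \code{mean}, \code{sd},
#'   \code{extrapolated}.
#' @export
predict.gpe <- function(object, newdata, ...) {
  Xn <- as_design_matrix(newdata)
  if (ncol(Xn) != ncol(object$X))
    stop(sprintf("newdata has %d columns, model was trained on %d",
                 ncol(Xn), ncol(object$X)))
  if (nrow(Xn) == 0)
    return(data.frame(mean = numeric(0), sd = numeric(0),
                      extrapolated = logical(0)))
  Xs <- sweep(sweep(Xn, 2, object$x_lo, "-"), 2, object$x_rng, "/")
  extrap <- apply(Xs < -1e-9 | Xs > 1 + 1e-9, 1, any)
  H <- cbind(1, Xs)
  Ks <- gpe_kernel(Xs, object$Xs, object$theta, object$kernel)
  mean_s <- as.numeric(H %*% object$beta_scaled + Ks %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Ks))   # so colSums(v^2) = k*' K^-1 k*
  D <- ncol(object$Xs)
  sf2 <- exp(object$theta[D + 1L])
  var_s <- pmax(0, sf2 - colSums(v^2))
  # GLS trend-uncertainty term
  R <- t(H) - crossprod(object$Kinv_H, t(Ks))
  var_s <- var_s + pmax(0, colSums(R * (object$Ainv %*% R)))
  data.frame(mean = object$y_mean + object$y_sd *
               (if (object$degenerate) rep(0, length(mean_s)) else mean_s),
             sd = object$y_sd *
               (if (object$degenerate) rep(0, length(var_s)) else sqrt(var_s)),
             extrapolated = extrap)
}

#' Sample the emulator posterior
#'
#' Draws from the posterior distribution at the given points. With
#' \code{joint = TRUE} draws come from the joint Gaussian posterior (dense
#' covariance; suitable for up to a few thousand points); with
#' \code{joint = FALSE} each point is drawn independently from its marginal,
#' which is the scalable scheme used when averaging sensitivity indices over
#' posterior draws on large Saltelli designs.
#'
#' @param object fitted \code{\link{gpe}}.
#' @param nsim number of posterior draws (>= 1).
#' @param seed integer seed.
#' @param newdata prediction points in native units.
#' @param joint draw jointly (TRUE) or per-point marginals (FALSE).
#' @param ... unused.
#' @return \code{nrow(newdata) x nsim} matrix of draws.
#' @export
simulate.gpe <- function(object, nsim = 1, seed = 1, newdata,
                         joint = TRUE, ...) {
  if (nsim < 1) stop("nsim must be >= 1")
  p <- predict(object, newdata)
  m <- nrow(p)
  if (!joint || object$degenerate) {
    Z <- with_seed(seed, matrix(stats::rnorm(m * nsim), m, nsim))
    return(p$mean + p$sd * Z)
  }
  Xn <- as_design_matrix(newdata)
  Xs <- sweep(sweep(Xn, 2, object$x_lo, "-"), 2, object$x_rng, "/")
  H <- cbind(1, Xs)
  Ks <- gpe_kernel(Xs, object$Xs, object$theta, object$kernel)
  Kss <- gpe_kernel(Xs, Xs, object$theta, object$kernel)
  v <- forwardsolve(t(object$L), t(Ks))
  C <- Kss - crossprod(v)
  R <- t(H) - crossprod(object$Kinv_H, t(Ks))
  C <- C + t(R) %*% object$Ainv %*% R
  C <- (C + t(C)) / 2 + diag(1e-10, m)
  Lc <- chol(C)
  Z <- with_seed(seed, matrix(stats::rnorm(m * nsim), m, nsim))
  p$mean + object$y_sd * crossprod(Lc, Z)
}

#' @export
print.gpe <- function(x, ...) {
  D <- ncol(x$X)
  cat(sprintf("Gaussian-process emulator (%s kernel), n = %d, D = %d\n",
              x$kernel, nrow(x$X), D))
  if (x$degenerate) cat("  [degenerate: constant training output]\n")
  cat(sprintf("  signal sd: %.4g, nugget sd: %.4g (scaled output units)\n",
              sqrt(exp(x$theta[D + 1L])), sqrt(exp(x$theta[D + 2L]))))
  invisible(x)
}

#' @export
summary.gpe <- function(object, ...) {
  D <- ncol(object$X)
  out <- list(
    n = nrow(object$X), D = D, kernel = object$kernel,
    degenerate = object$degenerate,
    lengthscales = stats::setNames(exp(object$theta[seq_len(D)]),
                                   colnames(object$X)),
    signal_var = unname(exp(object$theta[D + 1L])),
    nugget_var = unname(exp(object$theta[D + 2L])),
    beta = object$beta)
  class(out) <- "summary.gpe"
  out
}

#' @export
print.summary.gpe <- function(x, ...) {
  cat(sprintf("GPE: n = %d, D = %d, kernel = %s\n", x$n, x$D, x$kernel))
  cat("Linear-mean coefficients (native output units, unit-box inputs):\n")
  print(round(x$beta, 5))
  cat("Lengthscales (unit box):\n")
  print(round(x$lengthscales, 4))
  cat(sprintf("Signal variance %.4g, nugget variance %.4g (scaled)\n",
              x$signal_var, x$nugget_var))
  invisible(x)
}

#' @export
coef.gpe <- function(object, ...) object$beta

#' @export
residuals.gpe <- function(object, ...) {
  object$y - predict(object, object$X)$mean
}

#' @export
plot.gpe <- function(x, ...) {
  p <- predict(x, x$X)
  graphics::plot(x$y, p$mean, xlab = "simulator output",
                 ylab = "emulator posterior mean",
                 main = "GPE training fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

## ---- cross-validation --------------------------------------------------

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - RSS/TSS} between observations and point predictions, with
#' TSS taken about the observation mean.
#'
#' @param obs observed values.
#' @param pred predicted values.
#' @return scalar R-squared (<= 1; can be negative for poor predictions).
#' @export
r_squared <- function(obs, pred) {
  rss <- sum((obs - pred)^2)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) return(if (rss == 0) 1 else -Inf)
  1 - rss / tss
}

#' Independent standard error score
#'
#' Percentage of points whose observation lies strictly within two posterior
#' standard deviations of the posterior mean:
#' \eqn{ISE = 100 \cdot \#\{|E[f(x)|D] - Y| < 2\sigma[f(x)|D]\} / n}.
#'
#' @param obs observed values.
#' @param mean posterior means.
#' @param sd posterior standard deviations.
#' @return percentage in [0, 100].
#' @export
ise_score <- function(obs, mean, sd) {
  100 * base::mean(abs(mean - obs) < 2 * sd)
}

#' k-fold cross-validation of a Gaussian-process emulator
#'
#' Splits the training data into \code{k_folds} seeded folds, refits the
#' emulator on each training split and scores the held-out points with
#' \code{\link{r_squared}} (point accuracy) and \code{\link{ise_score}}
#' (uncertainty calibration).
#'
#' @param X,y training data as in \code{\link{gpe}}.
#' @param k_folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param ... further arguments passed to \code{\link{gpe}}.
#' @return object of class \code{"gpe_cv"}: data.frame of per-fold scores
#'   plus \code{mean_r2} and \code{mean_ise}.
#' @export
cross_validate <- function(X, y, k_folds = 5, seed = 1, ...) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  X <- as_design_matrix(X)
  n <- nrow(X)
  if (n < 2 * k_folds) stop("not enough rows for the requested folds")
  fold <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  scores <- data.frame(fold = seq_len(k_folds), r2 = NA_real_,
                       ise = NA_real_)
  for (k in seq_len(k_folds)) {
    te <- fold == k
    fit <- gpe(X[!te, , drop = FALSE], y[!te], seed = seed, ...)
    p <- predict(fit, X[te, , drop = FALSE])
    scores$r2[k] <- r_squared(y[te], p$mean)
    scores$ise[k] <- ise_score(y[te], p$mean, p$sd)
  }
  structure(list(folds = scores, mean_r2 = mean(scores$r2),
                 mean_ise = mean(scores$ise), k_folds = k_folds,
                 seed = seed),
            class = "gpe_cv")
}

#' @export
print.gpe_cv <- function(x, ...) {
  cat(sprintf("%d-fold GPE cross-validation (seed %d)\n", x$k_folds, x$seed))
  print(transform(x$folds, r2 = round(r2, 4), ise = round(ise, 1)))
  cat(sprintf("mean R^2 = %.4f, mean ISE = %.1f%%\n", x$mean_r2, x$mean_ise))
  invisible(x)
}
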
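#' Guccione passive-material parameters
#'
#' Transversely isotropic exponential strain-energy law for passive
#' myocardium,
#' \deqn{\Psi(E) = \frac{a}{2}\left[e^Q - 1\right] +
#'       \frac{\kappa}{2}(\log J)^2,}
#' \deqn{Q = b_f E_{ff}^2 + 2 b_{ft}(E_{fs}^2 + E_{fn}^2) +
#'       b_t (E_{ss}^2 + E_{nn}^2 + 2 E_{sn}^2),}
#' in fibre (f), sheet (s) and sheet-normal (n) coordinates, with bulk
#' modulus \eqn{\kappa} enforcing near incompressibility.
#'
#' @param a bulk stiffness (kPa).
#' @param b_f,b_ft,b_t fibre, fibre-transverse shear and transverse
#'   stiffness exponents.
#' @param kappa bulk modulus (kPa), default 1000.
#' @return list of class \code{"guccione_params"}.
#' @export
guccione_params <- function(a = 1.0, b_f = 8.0, b_ft = 4.0, b_t = 3.0,
                            kappa = 1000) {
  if (any(c(a, b_f, b_ft, b_t, kappa) <= 0))
    stop("all Guccione parameters must be positive")
  structure(list(a = a, b_f = b_f, b_ft = b_ft, b_t = b_t, kappa = kappa),
            class = "guccione_params")
}

# coerce E input (3x3 matrix, or named components) to a 3x3 symmetric matrix
as_strain <- function(E) {
  if (is.matrix(E)) {
    stopifnot(all(dim(E) == c(3, 3)))
    if (max(abs(E - t(E))) > 1e-12) stop("strain tensor must be symmetric")
    return(E)
  }
  comp <- c(ff = 0, ss = 0, nn = 0, fs = 0, fn = 0, sn = 0)
  comp[names(E)] <- E
  matrix(c(comp["ff"], comp["fs"], comp["fn"],
           comp["fs"], comp["ss"], comp["sn"],
           comp["fn"], comp["sn"], comp["nn"]), 3, 3)
}

guccione_Q <- function(E, p) {
  p$b_f * E[1, 1]^2 + 2 * p$b_ft * (E[1, 2]^2 + E[1, 3]^2) +
    p$b_t * (E[2, 2]^2 + E[3, 3]^2 + 2 * E[2, 3]^2)
}

#' Guccione strain energy
#'
#' @param E Green-Lagrange strain in fibre coordinates: a symmetric 3x3
#'   matrix or a named vector with any of \code{ff, ss, nn, fs, fn, sn}.
#' @param J determinant of the deformation gradient (> 0).
#' @param params \code{\link{guccione_params}}.
#' @return strain energy density in kPa.
#' @export
strain_energy <- function(E, J = 1, params) {
  if (J <= 0) stop("J must be > 0")
  E <- as_strain(E)
  Q <- guccione_Q(E, params)
  params$a / 2 * (exp(Q) - 1) + params$kappa / 2 * log(J)^2
}

#' Second Piola-Kirchhoff stress of the Guccione law
#'
#' Analytic gradient of the deviatoric strain energy with respect to the
#' strain components (at fixed J), e.g.
#' \eqn{S_{ff} = a\, b_f E_{ff} e^Q}. Matches central finite differences
#' of \code{\link{strain_energy}} component-wise.
#'
#' @inheritParams strain_energy
#' @return symmetric 3x3 stress matrix (kPa) in fibre coordinates.
#' @export
pk2_stress <- function(E, J = 1, params) {
  if (J <= 0) stop("J must be > 0")
  E <- as_strain(E)
  Q <- guccione_Q(E, params)
  eQ <- exp(Q)
  a <- params$a
  S <- matrix(0, 3, 3)
  S[1, 1] <- a * params$b_f * E[1, 1] * eQ
  S[2, 2] <- a * params$b_t * E[2, 2] * eQ
  S[3, 3] <- a * params$b_t * E[3, 3] * eQ
  S[1, 2] <- S[2, 1] <- a * params$b_ft * E[1, 2] * eQ
  S[1, 3] <- S[3, 1] <- a * params$b_ft * E[1, 3] * eQ
  S[2, 3] <- S[3, 2] <- a * params$b_t * E[2, 3] * eQ
  dimnames(S) <- list(c("f", "s", "n"), c("f", "s", "n"))
  S
}

KPA_TO_MMHG <- 7.50062

# thin-wall equibiaxial inflation pressure (mmHg) at wall stretch lambda
thin_wall_pressure <- function(lambda, params, wall_volume_ml,
                               unloaded_volume_ml) {
  Eff <- (lambda^2 - 1) / 2
  Enn <- (lambda^-4 - 1) / 2
  Q <- params$b_f * Eff^2 + params$b_t * (Eff^2 + Enn^2)
  eQ <- exp(pmin(Q, 50))
  S_ff <- params$a * params$b_f * Eff * eQ
  S_ss <- params$a * params$b_t * Eff * eQ
  S_nn <- params$a * params$b_t * Enn * eQ
  sig <- lambda^2 * (S_ff + S_ss) / 2 - lambda^-4 * S_nn  # kPa
  r0 <- (3 * unloaded_volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  h0 <- wall_volume_ml * 1000 / (4 * pi * r0^2)
  2 * sig * (h0 / lambda^2) / (r0 * lambda) * KPA_TO_MMHG
}

#' Inflate a thin-wall chamber to a given pressure
#'
#' Solves the Laplace-type equilibrium of a thin-wall sphere with an
#' incompressible Guccione wall under equibiaxial stretch: finds the wall
#' stretch \eqn{\lambda \in [1, 3]} with cavity pressure equal to the
#' applied pressure (bisection to 1e-8 relative) and returns the inflated
#' cavity volume \eqn{V_0 \lambda^3} and the fibre Green strain.
#'
#' @param params \code{\link{guccione_params}}.
#' @param wall_volume wall volume (mL).
#' @param unloaded_volume unloaded cavity volume (mL).
#' @param pressure cavity pressure (mmHg, >= 0).
#' @return list with \code{volume} (mL), \code{fibre_strain} and
#'   \code{lambda}.
#' @export
inflate_chamber <- function(params, wall_volume, unloaded_volume, pressure) {
  stopifnot(inherits(params, "guccione_params"), wall_volume > 0,
            unloaded_volume > 0)
  if (pressure < 0) stop("pressure must be >= 0")
  if (pressure == 0)
    return(list(volume = unloaded_volume, fibre_strain = 0, lambda = 1))
  f <- function(l) thin_wall_pressure(l, params, wall_volume,
                                      unloaded_volume) - pressure
  if (f(3) < 0)
    stop("no equilibrium for lambda in [1, 3]: pressure beyond model validity")
  lam <- stats::uniroot(f, c(1, 3), tol = 1e-8 * 3)$root
  list(volume = unloaded_volume * lam^3, fibre_strain = (lam^2 - 1) / 2,
       lambda = lam)
}

#' Unload a chamber from its end-diastolic state
#'
#' Finds the unloaded cavity volume whose inflation to the end-diastolic
#' pressure recovers the loaded volume (bisection to 1e-6 relative): the
#' lumped analogue of backward-displacement unloading of a meshed
#' chamber.
#'
#' @param params \code{\link{guccione_params}}.
#' @param wall_volume wall volume (mL).
#' @param loaded_volume measured end-diastolic cavity volume (mL).
#' @param edp end-diastolic pressure (mmHg, >= 0).
#' @return unloaded cavity volume (mL).
#' @export
unload_chamber <- function(params, wall_volume, loaded_volume, edp) {
  stopifnot(loaded_volume > 0)
  if (edp < 0) stop("edp must be >= 0")
  if (edp == 0) return(loaded_volume)
  g <- function(v0) inflate_chamber(params, wall_volume, v0, edp)$volume -
    loaded_volume
  lo <- loaded_volume / 27  # lambda = 3 at the lower end
  if (g(lo) > 0)
    stop("no unloaded volume in (0, loaded_volume]: pressure too high")
  stats::uniroot(g, c(lo, loaded_volume), tol = 1e-6 * loaded_volume)$root
}
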
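#' Calcium-transient surrogate parameters
#'
#' Phenomenological description of the intracellular calcium transient:
#' a diastolic level plus a double-exponential beat shape normalised to
#' unit peak. Three multipliers map ionic-model conductances onto the
#' transient: \code{amp_scale} scales the amplitude (the role of the
#' L-type calcium conductance), \code{decay_scale} stretches the decay
#' time constant (the role of the sodium-calcium exchanger / SR uptake),
#' and \code{buffer_scale} scales troponin binding kinetics in the tension
#' model (the role of the total troponin concentration).
#'
#' @param ca_dias diastolic calcium (uM).
#' @param ca_amp transient amplitude at unit \code{amp_scale} (uM).
#' @param tau_rise,tau_decay upstroke and decay time constants (ms),
#'   \code{tau_rise < tau_decay}.
#' @param amp_scale,decay_scale,buffer_scale positive multipliers.
#' @return list of class \code{"calcium_params"}.
#' @export
calcium_params <- function(ca_dias = 0.1, ca_amp = 1.0, tau_rise = 10,
                           tau_decay = 60, amp_scale = 1,
                           decay_scale = 1, buffer_scale = 1) {
  vals <- c(ca_dias, ca_amp, tau_rise, tau_decay, amp_scale, decay_scale,
            buffer_scale)
  if (any(vals <= 0)) stop("all calcium parameters must be positive")
  if (tau_rise >= tau_decay * decay_scale)
    stop("tau_rise must be smaller than the effective decay constant")
  structure(list(ca_dias = ca_dias, ca_amp = ca_amp, tau_rise = tau_rise,
                 tau_decay = tau_decay, amp_scale = amp_scale,
                 decay_scale = decay_scale, buffer_scale = buffer_scale),
            class = "calcium_params")
}

#' Active-tension surrogate parameters
#'
#' Parameters of the calcium-to-tension scheme: troponin binding
#' (\code{k_trpn}, \code{ca50}, \code{n_trpn}), thin-filament regulation
#' (\code{trpn50}, \code{n_tm}, \code{k_u}), a three-state
#' unbound/weak/strong crossbridge pool whose on-rates are scaled by
#' \code{nu} (U to W) and \code{mu} (W to S) and whose off-rates pin the
#' sustained-activation steady state at duty ratio \code{r_s} with
#' W/S ratio \code{r_w}, the reference isometric tension \code{T_ref},
#' and the velocity-dependence pair \code{A_eff}, \code{phi}. The
#' length-dependence parameters \code{beta_0}, \code{beta_1} and the
#' distortion rates \code{gamma_s}, \code{gamma_w} are accepted for
#' interface completeness but are inert in the isometric surrogate.
#'
#' @param T_ref reference isometric tension (kPa).
#' @param ca50 calcium sensitivity (uM).
#' @param n_trpn calcium-troponin cooperativity (>= 1).
#' @param k_trpn troponin unbinding rate (1/ms).
#' @param trpn50 bound-troponin fraction at half regulation.
#' @param n_tm regulation Hill coefficient (>= 1).
#' @param k_u blocked-to-unblocked transition rate (1/ms).
#' @param nu,mu crossbridge on-rate scalings.
#' @param r_s steady-state duty ratio in (0, 1).
#' @param r_w steady-state W/S ratio (> 0); requires
#'   \code{r_s * (1 + r_w) < 1}.
#' @param kb base crossbridge cycling rate (1/ms).
#' @param A_eff velocity-dependence scale.
#' @param phi distortion decay of the velocity factor.
#' @param beta_0,beta_1,gamma_s,gamma_w accepted, inert in isometric runs.
#' @return list of class \code{"land_params"}.
#' @export
land_params <- function(T_ref = 120, ca50 = 0.55, n_trpn = 2, k_trpn = 0.1,
                        trpn50 = 0.35, n_tm = 2.2, k_u = 0.03, nu = 7,
                        mu = 3, r_s = 0.25, r_w = 0.5, kb = 0.004,
                        A_eff = 25, phi = 2.23, beta_0 = 2.3,
                        beta_1 = -2.4, gamma_s = 0.0085,
                        gamma_w = 0.615) {
  if (r_s <= 0 || r_s >= 1) stop("r_s must be in (0, 1)")
  if (r_w <= 0) stop("r_w must be > 0")
  if (r_s * (1 + r_w) >= 1) stop("r_s * (1 + r_w) must be < 1")
  if (n_trpn < 1 || n_tm < 1) stop("Hill exponents must be >= 1")
  if (any(c(T_ref, ca50, k_trpn, trpn50, k_u, nu, mu, kb) <= 0))
    stop("rates and scales must be > 0")
  structure(list(T_ref = T_ref, ca50 = ca50, n_trpn = n_trpn,
                 k_trpn = k_trpn, trpn50 = trpn50, n_tm = n_tm, k_u = k_u,
                 nu = nu, mu = mu, r_s = r_s, r_w = r_w, kb = kb,
                 A_eff = A_eff, phi = phi, beta_0 = beta_0,
                 beta_1 = beta_1, gamma_s = gamma_s, gamma_w = gamma_w),
            class = "land_params")
}

#' Simulate the calcium transient to steady state
#'
#' Per beat the transient is
#' \eqn{Ca(t) = Ca_{dias} + Ca_{amp} \cdot amp\_scale \cdot g(t)} with
#' \eqn{g} a double exponential
#' \eqn{e^{-t/(\tau_{decay} \cdot decay\_scale)} - e^{-t/\tau_{rise}}}
#' normalised to unit peak. Beats superpose additively (the decaying tail
#' of earlier beats carries into the next cycle); pacing continues until
#' the beat-to-beat peak change drops below 0.1% or \code{n_beats} is
#' reached.
#'
#' @param params \code{\link{calcium_params}}.
#' @param bcl basic cycle length (ms).
#' @param n_beats maximum number of paced beats.
#' @param dt time step of the output grid (ms).
#' @return data.frame of class \code{"transient"} with columns \code{t}
#'   (ms, one steady-state beat starting at activation) and \code{value}
#'   (uM); attributes \code{bcl}, \code{converged}, \code{beats_run},
#'   \code{dt}.
#' @export
simulate_calcium <- function(params, bcl = 854, n_beats = 50, dt = 0.02) {
  stopifnot(inherits(params, "calcium_params"), bcl > 0, n_beats >= 1)
  tau_d <- params$tau_decay * params$decay_scale
  tau_r <- params$tau_rise
  tt <- seq(0, bcl - dt, by = dt)
  g1 <- exp(-tt / tau_d) - exp(-tt / tau_r)
  t_pk <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
  g_max <- exp(-t_pk / tau_d) - exp(-t_pk / tau_r)
  g1 <- g1 / g_max
  # additive superposition of previous-beat tails
  g <- g1
  peak_prev <- max(g)
  converged <- FALSE
  beats <- 1L
  decay_per_beat <- exp(-bcl / tau_d)
  tail_term <- (exp(-(tt + bcl) / tau_d) - exp(-(tt + bcl) / tau_r)) / g_max
  while (beats < n_beats) {
    g <- g1 + (g - g1) * decay_per_beat + tail_term
    beats <- beats + 1L
    peak <- max(g)
    if (abs(peak - peak_prev) / peak < 0.001) { converged <- TRUE; break }
    peak_prev <- peak
  }
  if (!converged && n_beats > 1)
    warning(sprintf("calcium not converged in %d beats (last peak delta %.3g)",
                    n_beats, abs(max(g) - peak_prev)))
  out <- data.frame(t = tt, value = params$ca_dias +
                      params$ca_amp * params$amp_scale * g)
  structure(out, bcl = bcl, converged = converged || n_beats == 1L,
            beats_run = beats, dt = dt, buffer_scale = params$buffer_scale,
            class = c("transient", "data.frame"))
}

#' Simulate the isometric active-tension transient
#'
#' Integrates the crossbridge scheme (explicit RK4, compiled) driven by a
#' periodic calcium transient, running repeated beats from the resting
#' state until the peak tension is beat-to-beat stable, and returns the
#' last beat. Tension is normalised so that saturating calcium drives it
#' to \code{T_ref}. An optional normalised shortening-velocity series
#' applies the factor \eqn{\max(0, \min(1, 1 - A_{eff}\tanh(\phi v)))}.
#'
#' @param ca a calcium \code{"transient"} (one steady-state beat).
#' @param params \code{\link{land_params}}.
#' @param velocity optional velocity series on the same grid.
#' @param n_beats maximum paced beats.
#' @param buffer_scale troponin-kinetics multiplier; defaults to the value
#'   recorded on the calcium transient (the role of the total troponin
#'   concentration).
#' @return data.frame of class \code{"transient"} with columns \code{t},
#'   \code{value} (kPa); attribute \code{states} holds the final-beat
#'   state trajectories (CaTRPN, permissive, W, S).
#' @export
simulate_tension <- function(ca, params, velocity = NULL, n_beats = 10,
                             buffer_scale = NULL) {
  stopifnot(inherits(ca, "transient"), inherits(params, "land_params"))
  if (is.null(buffer_scale))
    buffer_scale <- if (is.null(attr(ca, "buffer_scale"))) 1
                    else attr(ca, "buffer_scale")
  dt <- attr(ca, "dt")
  vel <- if (is.null(velocity)) numeric(0) else as.numeric(velocity)
  pars <- c(unclass(params), list(buffer_scale = buffer_scale))
  state <- c(0, 0, 0, 0)
  peak_prev <- -Inf
  res <- NULL
  for (b in seq_len(n_beats)) {
    res <- .tension_integrate_cpp(ca$value, dt, pars, vel, state)
    state <- res$states[nrow(res$states), ]
    peak <- max(res$tension)
    if (is.finite(peak_prev) && peak > 0 &&
        abs(peak - peak_prev) / max(peak, 1e-12) < 0.001) break
    peak_prev <- peak
  }
  out <- data.frame(t = ca$t, value = res$tension)
  structure(out, bcl = attr(ca, "bcl"), dt = dt, states = res$states,
            class = c("transient", "data.frame"))
}

#' Features of a periodic transient
#'
#' Computes the standard beat features on a single steady-state beat that
#' starts at activation: peak, rest value (at activation onset),
#' amplitude, time to peak, duration to 90% recovery toward the rest
#' value, and the maximum upstroke derivative.
#'
#' @param series a \code{"transient"} (columns \code{t}, \code{value}) or
#'   any two-column data.frame on a uniform grid.
#' @return named numeric vector: \code{peak}, \code{rest},
#'   \code{amplitude}, \code{time_to_peak}, \code{duration_90},
#'   \code{max_dvdt}.
#' @export
transient_features <- function(series) {
  t <- series[[1]]; v <- series[[2]]
  stopifnot(length(t) >= 3)
  dt <- t[2] - t[1]
  rest <- v[1]
  ipk <- which.max(v)
  peak <- v[ipk]
  amp <- peak - rest
  dur <- 0
  if (amp > 0) {
    thresh <- rest + 0.1 * amp
    after <- which(seq_along(v) > ipk & v <= thresh)
    dur <- if (length(after)) t[after[1]] else t[length(t)]
  }
  c(peak = peak, rest = rest, amplitude = amp,
    time_to_peak = t[ipk] - t[1],
    duration_90 = dur,
    max_dvdt = if (length(v) > 1) max(diff(v)) / dt else 0)
}
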
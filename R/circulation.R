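#' Closed-loop circulation parameters
#'
#' Parameters of the four-chamber lumped circulation: chamber wall
#' volumes, valve and outlet orifice areas, the four elastic tubes (aorta,
#' pulmonary artery, systemic and pulmonary veins) with power-law
#' pressure-volume behaviour, reference systemic/pulmonary pressure drops
#' and flow, resistance scaling factors, and the pericardial volume
#' penalty. Defaults are the patient-derived constants of the study
#' configuration (stroke volume 70 mL at a basic cycle length of 854 ms
#' gives the reference systemic flow of 82 mL/s).
#'
#' @param V_LV_wall,V_RV_wall,V_SV_wall,V_LA_wall,V_RA_wall wall volumes
#'   (mL); the septal wall is shared between the ventricles.
#' @param AMVopen,ATVopen,AAVopen,APVopen,ASOopen,APOopen open orifice
#'   areas (mm^2) of the mitral, tricuspid, aortic and pulmonary valves
#'   and the systemic/pulmonary venous outlets.
#' @param pAo0,pPa0,pVe0,pPve0 scaling factors for the tube reference
#'   pressures.
#' @param l_Ao,l_Pa,l_Ve,l_Pve tube lengths (mm).
#' @param k_Ao,k_Pa,k_Ve,k_Pve tube stiffness exponents.
#' @param q_ref reference systemic flow (mL/s).
#' @param dp_sys_ref,dp_pulm_ref reference systemic and pulmonary pressure
#'   drops (mmHg).
#' @param R_sys,R_pulm resistance scaling factors in [1, 4].
#' @param k_peri pericardial stiffness (kPa/mm).
#' @param T_ref_LvRv RV/LV scaling of the reference tension in [0.5, 1].
#' @param a_LvRv RV/LV scaling of the bulk passive stiffness in [1, 2].
#' @param A_peri effective pericardial area (mm^2).
#' @param V_peri_ref total cardiac volume (mL) above which the pericardial
#'   penalty engages.
#' @param p_ref_Ao,p_ref_Pa,p_ref_Ve,p_ref_Pve internal tube reference
#'   pressures (mmHg) at the reference volumes.
#' @param bcl basic cycle length (ms).
#' @param av_delay atrioventricular delay (ms).
#' @return list of class \code{"circ_params"}.
#' @export
circ_params <- function(V_LV_wall = 93.6, V_RV_wall = 37.6,
                        V_SV_wall = 32.4, V_LA_wall = 25.7,
                        V_RA_wall = 22.2,
                        AMVopen = 508.3, ATVopen = 508.3, AAVopen = 336.7,
                        APVopen = 336.7, ASOopen = 518.7, APOopen = 296.1,
                        pAo0 = 1, pPa0 = 1, pVe0 = 1, pPve0 = 1,
                        l_Ao = 400, l_Pa = 200.06, l_Ve = 400.11,
                        l_Pve = 200.06,
                        k_Ao = 8, k_Pa = 8, k_Ve = 10, k_Pve = 10,
                        q_ref = 82, dp_sys_ref = 90.01,
                        dp_pulm_ref = 11.25,
                        R_sys = 1, R_pulm = 1,
                        k_peri = 1, T_ref_LvRv = 0.75, a_LvRv = 1.5,
                        A_peri = 2000, V_peri_ref = 200,
                        p_ref_Ao = 92.5, p_ref_Pa = 16, p_ref_Ve = 2.5,
                        p_ref_Pve = 4.75,
                        bcl = 854, av_delay = 150) {
  p <- lapply(as.list(environment()), function(v) unname(as.numeric(v)))
  if (any(unlist(p) <= 0)) stop("all circulation parameters must be positive")
  if (R_sys < 1 || R_sys > 4 || R_pulm < 1 || R_pulm > 4)
    stop("resistance scalings must lie in [1, 4]")
  structure(p, class = "circ_params")
}

#' Default per-chamber passive descriptions
#'
#' Chamber wall stiffness (Guccione), wall volumes (ventricles share the
#' septal wall) and unloaded cavity volumes used by the circulation's
#' thin-wall pressure law. The RV bulk stiffness is scaled by
#' \code{a_LvRv}.
#'
#' @param params \code{\link{circ_params}}.
#' @param a_V,b_t_V ventricular bulk and transverse stiffness.
#' @param a_A,b_f_A,b_t_A atrial stiffness parameters.
#' @param V0_LV,V0_RV,V0_LA,V0_RA unloaded cavity volumes (mL).
#' @return named list (LV, RV, LA, RA) of chamber descriptions.
#' @export
default_chamber_passive <- function(params = circ_params(),
                                    a_V = 1.0, b_t_V = 3.0,
                                    a_A = 2.0, b_f_A = 8.0, b_t_A = 3.0,
                                    V0_LV = 55, V0_RV = 65,
                                    V0_LA = 30, V0_RA = 30) {
  list(
    LV = list(guccione = guccione_params(a = a_V, b_f = 8, b_t = b_t_V),
              wall_volume = params$V_LV_wall + params$V_SV_wall,
              unloaded_volume = V0_LV),
    RV = list(guccione = guccione_params(a = a_V * params$a_LvRv, b_f = 8,
                                         b_t = b_t_V),
              wall_volume = params$V_RV_wall + params$V_SV_wall,
              unloaded_volume = V0_RV),
    LA = list(guccione = guccione_params(a = a_A, b_f = b_f_A, b_t = b_t_A),
              wall_volume = params$V_LA_wall, unloaded_volume = V0_LA),
    RA = list(guccione = guccione_params(a = a_A, b_f = b_f_A, b_t = b_t_A),
              wall_volume = params$V_RA_wall, unloaded_volume = V0_RA))
}

#' Default cell-tension drivers for the four chambers
#'
#' Runs the calcium and tension surrogates at the ventricular and atrial
#' default parameter sets and returns one steady-state tension beat per
#' chamber type on a coarse drive grid.
#'
#' @param bcl basic cycle length (ms).
#' @param ventricular,atrial \code{\link{land_params}} for the two chamber
#'   types.
#' @param ca_v,ca_a \code{\link{calcium_params}} for the two chamber types.
#' @param dt integration step (ms).
#' @return list with elements \code{LV}, \code{RV}, \code{LA}, \code{RA}
#'   (tension \code{"transient"} objects).
#' @export
default_tension_drivers <- function(bcl = 854,
                                    ventricular = land_params(),
                                    atrial = land_params(T_ref = 60),
                                    ca_v = calcium_params(),
                                    ca_a = calcium_params(tau_decay = 45),
                                    dt = 0.05) {
  ca_vent <- simulate_calcium(ca_v, bcl = bcl, dt = dt)
  ca_atr <- simulate_calcium(ca_a, bcl = bcl, dt = dt)
  tv <- simulate_tension(ca_vent, ventricular)
  ta <- simulate_tension(ca_atr, atrial)
  list(LV = tv, RV = tv, LA = ta, RA = ta)
}

#' Build a closed-loop four-chamber circuit
#'
#' Assembles the lumped circulation from its parameters, the per-chamber
#' passive descriptions, the cell tension drivers and the activation
#' pattern. The chamber pressure is the thin-wall Guccione passive law
#' plus a one-fibre-type active term
#' \eqn{(1/3)\,T_{drive}(t)\ln(1 + V_{wall}/V)} plus the shared
#' pericardial penalty; the tension drive of each chamber is the cell
#' transient averaged over activation offsets spread uniformly across
#' \code{[onset, onset + TAT]}, and the RV drive is scaled by
#' \code{T_ref_LvRv}.
#'
#' @param params \code{\link{circ_params}}.
#' @param chamber_passive as \code{\link{default_chamber_passive}}.
#' @param tension_drivers list of tension transients per chamber
#'   (LV, RV, LA, RA) sharing the circuit's basic cycle length.
#' @param activation named list per chamber with \code{onset} and
#'   \code{tat} (ms); defaults: atria at 0, ventricles at the AV delay,
#'   smearing of 60 ms (ventricles) / 40 ms (atria).
#' @param n_drive drive-grid resolution over one beat.
#' @return object of class \code{"circuit"}.
#' @export
build_circuit <- function(params = circ_params(),
                          chamber_passive = default_chamber_passive(params),
                          tension_drivers = default_tension_drivers(params$bcl),
                          activation = NULL, n_drive = 854) {
  stopifnot(inherits(params, "circ_params"))
  bcl <- params$bcl
  bcls <- vapply(tension_drivers, function(d) attr(d, "bcl"), numeric(1))
  if (any(abs(bcls - bcl) > 1e-9))
    stop("tension drivers must share the circuit basic cycle length")
  if (is.null(activation))
    activation <- list(
      LV = list(onset = params$av_delay, tat = 60),
      RV = list(onset = params$av_delay, tat = 60),
      LA = list(onset = 0, tat = 40),
      RA = list(onset = 0, tat = 40))
  chambers <- c("LV", "RV", "LA", "RA")
  tg <- seq(0, bcl, length.out = n_drive + 1L)[-(n_drive + 1L)]
  drive <- matrix(0, n_drive, 4, dimnames = list(NULL, chambers))
  scale <- c(LV = 1, RV = params$T_ref_LvRv, LA = 1, RA = 1)
  for (ch in chambers) {
    d <- tension_drivers[[ch]]
    act <- activation[[ch]]
    offs <- act$onset + act$tat * (seq_len(15) - 0.5) / 15
    f <- stats::approxfun(c(d$t, bcl), c(d$value, d$value[1]), rule = 2)
    val <- rowMeans(vapply(offs, function(o) f((tg - o) %% bcl),
                           numeric(n_drive)))
    drive[, ch] <- scale[[ch]] * val
  }
  structure(list(params = params, chamber_passive = chamber_passive,
                 activation = activation, drive = drive, bcl = bcl),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("Closed-loop four-chamber circuit, BCL = %g ms, AV delay = %g ms\n",
              x$bcl, x$params$av_delay))
  cat(sprintf("  R_sys = %g, R_pulm = %g, k_peri = %g kPa/mm\n",
              x$params$R_sys, x$params$R_pulm, x$params$k_peri))
  invisible(x)
}

#' Run the closed-loop circulation for several beats
#'
#' Integrates the circuit with a fixed-step RK4 scheme (internal step
#' \code{dt_int}) and returns traces at \code{dt} resolution. A negative
#' or non-finite volume flags the run as failed (failures are data, not
#' errors). The beat-to-beat periodicity residual of the last two beats
#' is reported.
#'
#' @param circuit a \code{\link{build_circuit}} result.
#' @param n_beats number of beats (default 5, reaching near steady state).
#' @param dt output step (ms).
#' @param dt_int internal integration step (ms).
#' @param init optional named initial volume vector (mL) with entries
#'   \code{V_LV, V_RV, V_LA, V_RA, V_Ao, V_Pa, V_Ve, V_Pve}; defaults to
#'   moderately filled chambers and tubes at their reference volumes.
#' @return object of class \code{"circ_run"}: data.frame \code{traces}
#'   (time, chamber volumes/pressures, tube volumes/pressures, flows),
#'   \code{success}, \code{periodicity} (relative last-beat volume
#'   residual), and the circuit.
#' @export
run_beats <- function(circuit, n_beats = 5, dt = 1.0, dt_int = 0.1,
                      init = NULL) {
  stopifnot(inherits(circuit, "circuit"), n_beats >= 1)
  p <- circuit$params
  cp <- circuit$chamber_passive
  chambers <- c("LV", "RV", "LA", "RA")
  cpars <- list(
    a = vapply(chambers, function(ch) cp[[ch]]$guccione$a, numeric(1)),
    bf = vapply(chambers, function(ch) cp[[ch]]$guccione$b_f, numeric(1)),
    bt = vapply(chambers, function(ch) cp[[ch]]$guccione$b_t, numeric(1)),
    V0 = vapply(chambers, function(ch) cp[[ch]]$unloaded_volume, numeric(1)),
    Vwall = vapply(chambers, function(ch) cp[[ch]]$wall_volume, numeric(1)),
    p_ref = c(p$pAo0 * p$p_ref_Ao, p$pPa0 * p$p_ref_Pa,
              p$pVe0 * p$p_ref_Ve, p$pPve0 * p$p_ref_Pve),
    V_ref = c(p$AAVopen * p$l_Ao, p$APVopen * p$l_Pa,
              p$ASOopen * p$l_Ve, p$APOopen * p$l_Pve) / 1000,
    ktube = c(p$k_Ao, p$k_Pa, p$k_Ve, p$k_Pve),
    A_mv = p$AMVopen, A_av = p$AAVopen, A_tv = p$ATVopen,
    A_pv = p$APVopen, A_so = p$ASOopen, A_po = p$APOopen,
    r_sys = p$R_sys * p$dp_sys_ref / p$q_ref,
    r_pulm = p$R_pulm * p$dp_pulm_ref / p$q_ref,
    k_peri = p$k_peri, A_peri = p$A_peri, V_peri_ref = p$V_peri_ref)
  y0 <- c(1.8 * cpars$V0[1:2], 1.6 * cpars$V0[3:4], cpars$V_ref)
  if (!is.null(init)) {
    nm <- c("V_LV", "V_RV", "V_LA", "V_RA", "V_Ao", "V_Pa", "V_Ve",
            "V_Pve")
    stopifnot(all(nm %in% names(init)))
    y0 <- as.numeric(init[nm])
  }
  res <- .circ_run_cpp(cpars, circuit$drive, y0, as.integer(n_beats),
                       circuit$bcl, dt, dt_int)
  n <- res$n_out
  vols <- res$V[seq_len(n), , drop = FALSE]
  colnames(vols) <- c("V_LV", "V_RV", "V_LA", "V_RA",
                      "V_Ao", "V_Pa", "V_Ve", "V_Pve")
  pch <- res$p_chamber[seq_len(n), , drop = FALSE]
  colnames(pch) <- c("p_LV", "p_RV", "p_LA", "p_RA")
  ptb <- res$p_tube[seq_len(n), , drop = FALSE]
  colnames(ptb) <- c("p_Ao", "p_Pa", "p_Ve", "p_Pve")
  q <- res$q[seq_len(n), , drop = FALSE]
  colnames(q) <- c("q_MV", "q_AV", "q_TV", "q_PV", "q_SO", "q_PO",
                   "q_sys", "q_pulm")
  traces <- data.frame(time = res$time[seq_len(n)], vols, pch, ptb, q)
  periodicity <- NA_real_
  if (res$success && n_beats >= 2) {
    per_beat <- round(circuit$bcl / dt)
    last <- traces$V_LV[(n - per_beat + 1):n]
    prev <- traces$V_LV[(n - 2 * per_beat + 1):(n - per_beat)]
    periodicity <- max(abs(last - prev)) / max(abs(last))
  }
  structure(list(traces = traces, success = res$success,
                 periodicity = periodicity, circuit = circuit,
                 dt = dt, n_beats = n_beats),
            class = "circ_run")
}

#' Passive rest state of a circuit
#'
#' Constructs the initial volume vector at which every chamber and tube
#' sits at the same pressure, so with no active tension all pressure
#' differences — and hence all flows — vanish: the passive equilibrium of
#' the closed loop. The pericardial penalty is accounted for
#' self-consistently when it engages at the resulting volumes.
#'
#' @param circuit a \code{\link{build_circuit}} result.
#' @param pressure common rest pressure (mmHg, > 0).
#' @return named volume vector suitable for \code{run_beats(init = )}.
#' @export
rest_state <- function(circuit, pressure = 5) {
  stopifnot(inherits(circuit, "circuit"), pressure > 0)
  p <- circuit$params
  cp <- circuit$chamber_passive
  vols_at <- function(pp) vapply(c("LV", "RV", "LA", "RA"), function(ch)
    inflate_chamber(cp[[ch]]$guccione, cp[[ch]]$wall_volume,
                    cp[[ch]]$unloaded_volume, pp)$volume,
    numeric(1))
  # self-consistent with the pericardial penalty: the passive pressure
  # plus the shared pericardial pressure must equal the rest pressure;
  # total chamber pressure is increasing in the passive pressure, so
  # bisection is robust even for a stiff pericardium
  total_p <- function(p_pas) {
    excess <- max(0, sum(vols_at(p_pas)) - p$V_peri_ref)
    p_pas + p$k_peri * excess * 1000 / p$A_peri * 7.50062
  }
  if (total_p(pressure) <= pressure + 1e-12) {
    p_pas <- pressure                       # pericardium disengaged
  } else {
    p_pas <- stats::uniroot(function(x) total_p(x) - pressure,
                            c(1e-6, pressure), tol = 1e-10)$root
  }
  vols <- vols_at(p_pas)
  p_ref <- c(p$pAo0 * p$p_ref_Ao, p$pPa0 * p$p_ref_Pa,
             p$pVe0 * p$p_ref_Ve, p$pPve0 * p$p_ref_Pve)
  V_ref <- c(p$AAVopen * p$l_Ao, p$APVopen * p$l_Pa,
             p$ASOopen * p$l_Ve, p$APOopen * p$l_Pve) / 1000
  tubes <- V_ref * (pressure / p_ref)^(3 / c(p$k_Ao, p$k_Pa, p$k_Ve,
                                             p$k_Pve))
  stats::setNames(c(vols, tubes),
                  c("V_LV", "V_RV", "V_LA", "V_RA",
                    "V_Ao", "V_Pa", "V_Ve", "V_Pve"))
}

#' @export
print.circ_run <- function(x, ...) {
  cat(sprintf("Circulation run: %d beats, %s%s\n", x$n_beats,
              if (x$success) "completed" else "FAILED (negative volume)",
              if (is.finite(x$periodicity))
                sprintf(", last-beat periodicity residual %.3g", x$periodicity)
              else ""))
  invisible(x)
}

#' Pressure-volume features of the final beat
#'
#' Extracts the twenty whole-heart outputs from the last complete beat:
#' per ventricle the end-diastolic volume and pressure (at ventricular
#' activation onset), end-systolic (minimum) volume, peak pressure and
#' the extrema of the pressure derivative (centred differences); per
#' atrium the end-diastolic volume (just before atrial activation onset),
#' the end-systolic volume and peak pressure during the atrial
#' contraction window, and the maximum volume during the v-wave (while
#' the AV valve is closed).
#'
#' @param run a \code{\link{run_beats}} result (successful, >= 1 full
#'   beat).
#' @param atrial_window duration of the atrial contraction window (ms)
#'   from atrial activation onset; defaults to onset + smearing + 150 ms.
#' @return named numeric vector of the 20 features (volumes mL, pressures
#'   mmHg, derivatives mmHg/ms).
#' @export
pv_features <- function(run, atrial_window = NULL) {
  stopifnot(inherits(run, "circ_run"))
  if (!run$success) stop("failed run: no features")
  tr <- run$traces
  bcl <- run$circuit$bcl
  dt <- run$dt
  per_beat <- round(bcl / dt)
  n <- nrow(tr)
  if (n < per_beat + 1) stop("need at least one complete beat")
  idx <- (n - per_beat):n            # last beat, inclusive endpoints
  tau <- (tr$time[idx] - tr$time[idx[1]])  # 0 .. bcl
  act <- run$circuit$activation
  out <- c()
  dpdt <- function(pr) {
    d <- (pr[c(-1, -2)] - pr[seq_len(length(pr) - 2)]) / (2 * dt)
    range(d)
  }
  near <- function(tt) which.min(abs(tau - tt))
  for (ch in c("LV", "RV")) {
    V <- tr[[paste0("V_", ch)]][idx]
    P <- tr[[paste0("p_", ch)]][idx]
    i_on <- near(act[[ch]]$onset %% bcl)
    d <- dpdt(P)
    out <- c(out, stats::setNames(
      c(V[i_on], P[i_on], min(V), max(P), d[2], d[1]),
      paste0(c("EDV_", "EDP_", "ESV_", "p_max_", "dpdt_max_", "dpdt_min_"),
             ch)))
  }
  for (ch in c("LA", "RA")) {
    V <- tr[[paste0("V_", ch)]][idx]
    P <- tr[[paste0("p_", ch)]][idx]
    onset <- act[[ch]]$onset %% bcl
    win <- if (is.null(atrial_window)) act[[ch]]$tat + 150 else atrial_window
    in_win <- tau >= onset & tau <= onset + win
    avq <- tr[[if (ch == "LA") "q_MV" else "q_TV"]][idx]
    closed <- avq <= 0
    i_edv <- if (onset == 0) length(tau) else near(onset)
    out <- c(out, stats::setNames(
      c(V[i_edv], min(V[in_win]),
        if (any(closed)) max(V[closed]) else max(V),
        max(P[in_win])),
      paste0(c("EDV_", "ESV_", "EDV_vwave_", "p_max_"), ch)))
  }
  out
}
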
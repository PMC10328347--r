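#' Registered surrogate forward models
#'
#' Returns a registered desk-scale forward model: its parameter space and
#' a vectorised simulator mapping a design matrix to an output matrix
#' (rows failing with an error are returned as all-NA, mirroring failed
#' simulator runs).
#'
#' \describe{
#'   \item{eikonal}{tissue activation: conduction velocities, fast-region
#'     scalings and the AV delay map to total ventricular and atrial
#'     activation times on the two-slab geometry.}
#'   \item{ventricular_cell, atrial_cell}{calcium and isometric tension
#'     transient features from the cell surrogate (paced at 1 Hz, the
#'     cycle length used for cell-level analysis).}
#'   \item{passive}{passive inflation: chamber stiffness parameters map to
#'     inflated volumes and fibre strains at fixed end-diastolic
#'     pressures.}
#'   \item{circulation}{circulation parameters map to the twenty
#'     pressure-volume features at fixed default drivers.}
#' }
#'
#' @param name one of \code{"eikonal"}, \code{"ventricular_cell"},
#'   \code{"atrial_cell"}, \code{"passive"}, \code{"circulation"}.
#' @param bcl basic cycle length (ms) for the circulation model.
#' @return list with elements \code{name}, \code{space} and \code{fn}.
#' @export
forward_model <- function(name = c("eikonal", "ventricular_cell",
                                   "atrial_cell", "passive", "circulation"),
                          bcl = 854) {
  name <- match.arg(name)
  switch(name,
         eikonal = eikonal_model(),
         ventricular_cell = cell_model("ventricular"),
         atrial_cell = cell_model("atrial"),
         passive = passive_model(),
         circulation = circulation_model(bcl))
}

# rowwise simulator wrapper: errors become all-NA rows (failed runs)
rowwise_simulator <- function(row_fn, out_names) {
  function(X) {
    X <- as_design_matrix(X)
    Y <- matrix(NA_real_, nrow(X), length(out_names),
                dimnames = list(NULL, out_names))
    for (i in seq_len(nrow(X))) {
      y <- tryCatch(suppressWarnings(row_fn(X[i, ])),
                    error = function(e) NULL)
      if (!is.null(y) && all(is.finite(y))) Y[i, ] <- y[out_names]
    }
    Y
  }
}

eikonal_model <- function() {
  grid <- two_slab_geometry()
  space <- parameter_space(list(
    param_def("CV_f_v", "hm-constrained", bounds = c(0.3, 1.2),
              unit = "mm/ms", submodel = "tissue-ep"),
    param_def("k_FEC", "hm-constrained", bounds = c(1, 6),
              submodel = "tissue-ep"),
    param_def("CV_f_a", "hm-constrained", bounds = c(0.3, 1.2),
              unit = "mm/ms", submodel = "tissue-ep"),
    param_def("k_BB", "hm-constrained", bounds = c(1, 6),
              submodel = "tissue-ep"),
    param_def("AV_delay", "free", bounds = c(100, 200), unit = "ms",
              submodel = "tissue-ep")))
  fn <- rowwise_simulator(function(x) {
    f <- build_velocity_field(grid, cv_f_v = x["CV_f_v"],
                              cv_f_a = x["CV_f_a"], k_fec = x["k_FEC"],
                              k_bb = x["k_BB"])
    src <- data.frame(node = c(attr(grid, "atrial_site"),
                               attr(grid, "ventricular_site")),
                      t0 = c(0, x["AV_delay"]))
    m <- solve_eikonal(grid, f, src)
    c(TAT_v = total_activation_time(m, c("ventricular-myo", "FEC"), grid),
      TAT_a = total_activation_time(m, c("atrial-myo", "BB"), grid))
  }, c("TAT_v", "TAT_a"))
  list(name = "eikonal", space = space, fn = fn, grid = grid)
}

cell_model <- function(type = c("ventricular", "atrial"), bcl = 1000,
                       dt = 0.1) {
  type <- match.arg(type)
  sm <- if (type == "ventricular") "ventricular-cell" else "atrial-cell"
  t_ref_b <- if (type == "ventricular") c(60, 180) else c(30, 100)
  space <- parameter_space(list(
    param_def("amp_scale", "hm-constrained", bounds = c(0.5, 2),
              submodel = sm),
    param_def("decay_scale", "hm-constrained", bounds = c(0.5, 2),
              submodel = sm),
    param_def("buffer_scale", "hm-constrained", bounds = c(0.5, 2),
              submodel = sm),
    param_def("T_ref", "hm-constrained", bounds = t_ref_b, unit = "kPa",
              submodel = sm),
    param_def("ca50", "hm-constrained", bounds = c(0.35, 0.9), unit = "uM",
              submodel = sm),
    param_def("trpn50", "hm-constrained", bounds = c(0.2, 0.5),
              submodel = sm),
    param_def("mu", "hm-constrained", bounds = c(1, 8), submodel = sm),
    param_def("r_s", "hm-constrained", bounds = c(0.1, 0.4),
              submodel = sm),
    param_def("r_w", "hm-constrained", bounds = c(0.2, 0.9),
              submodel = sm)))
  base_ca <- if (type == "ventricular") calcium_params()
             else calcium_params(tau_decay = 45)
  fn <- rowwise_simulator(function(x) {
    cp <- calcium_params(ca_dias = base_ca$ca_dias, ca_amp = base_ca$ca_amp,
                         tau_rise = base_ca$tau_rise,
                         tau_decay = base_ca$tau_decay,
                         amp_scale = x["amp_scale"],
                         decay_scale = x["decay_scale"],
                         buffer_scale = x["buffer_scale"])
    lp <- land_params(T_ref = x["T_ref"], ca50 = x["ca50"],
                      trpn50 = x["trpn50"], mu = x["mu"], r_s = x["r_s"],
                      r_w = x["r_w"])
    ca <- simulate_calcium(cp, bcl = bcl, dt = dt)
    tn <- simulate_tension(ca, lp)
    fc <- transient_features(ca); ft <- transient_features(tn)
    c(ca_peak = unname(fc["peak"]), ca_dur = unname(fc["duration_90"]),
      T_peak = unname(ft["peak"]), T_ttp = unname(ft["time_to_peak"]),
      T_dur = unname(ft["duration_90"]))
  }, c("ca_peak", "ca_dur", "T_peak", "T_ttp", "T_dur"))
  list(name = paste0(type, "_cell"), space = space, fn = fn)
}

passive_model <- function() {
  space <- parameter_space(list(
    param_def("a_V", "free", bounds = c(0.5, 1.5), unit = "kPa",
              submodel = "passive"),
    param_def("b_t_V", "free", bounds = c(1.5, 4.5), submodel = "passive"),
    param_def("a_A", "free", bounds = c(1.5, 2.5), unit = "kPa",
              submodel = "passive"),
    param_def("b_f_A", "free", bounds = c(4, 12), submodel = "passive")))
  cpars <- circ_params()
  fn <- rowwise_simulator(function(x) {
    gv <- guccione_params(a = x["a_V"], b_f = 8, b_t = x["b_t_V"])
    ga <- guccione_params(a = x["a_A"], b_f = x["b_f_A"], b_t = 3)
    lv <- inflate_chamber(gv, cpars$V_LV_wall + cpars$V_SV_wall, 55, 10)
    rv <- inflate_chamber(gv, cpars$V_RV_wall + cpars$V_SV_wall, 65, 5)
    la <- inflate_chamber(ga, cpars$V_LA_wall, 30, 8)
    c(V_LV_infl = lv$volume, V_RV_infl = rv$volume, V_LA_infl = la$volume,
      strain_LV = lv$fibre_strain, strain_LA = la$fibre_strain)
  }, c("V_LV_infl", "V_RV_infl", "V_LA_infl", "strain_LV", "strain_LA"))
  list(name = "passive", space = space, fn = fn)
}

circulation_model <- function(bcl = 854) {
  space <- parameter_space(list(
    param_def("R_sys", "free", bounds = c(1, 4), submodel = "circulation"),
    param_def("R_pulm", "free", bounds = c(1, 4), submodel = "circulation"),
    param_def("l_Ao", "free", bounds = c(300, 500), unit = "mm",
              submodel = "circulation"),
    param_def("k_Ao", "free", bounds = c(6, 10), submodel = "circulation"),
    param_def("T_ref_LvRv", "free", bounds = c(0.5, 1),
              submodel = "circulation"),
    param_def("a_LvRv", "free", bounds = c(1, 2), submodel = "circulation"),
    param_def("k_peri", "free", bounds = c(0.5, 2), unit = "kPa/mm",
              submodel = "boundary"),
    param_def("a_V", "free", bounds = c(0.5, 1.5), unit = "kPa",
              submodel = "passive")))
  drivers <- default_tension_drivers(bcl)
  fn <- rowwise_simulator(function(x) {
    pars <- circ_params(R_sys = x["R_sys"], R_pulm = x["R_pulm"],
                        l_Ao = x["l_Ao"], k_Ao = x["k_Ao"],
                        T_ref_LvRv = x["T_ref_LvRv"],
                        a_LvRv = x["a_LvRv"], k_peri = x["k_peri"],
                        bcl = bcl)
    cpas <- default_chamber_passive(pars, a_V = x["a_V"])
    run <- run_beats(build_circuit(pars, cpas, drivers))
    if (!run$success) stop("failed run")
    pv_features(run)
  }, names(pv_features(run_beats(build_circuit(
    circ_params(bcl = bcl), tension_drivers = drivers)))))
  list(name = "circulation", space = space, fn = fn)
}

#' Desk-scale composite forward chain
#'
#' The hierarchical whole-organ simulator at desk scale: a 12-parameter
#' chain running tissue activation (total activation times and AV delay),
#' the ventricular and atrial cell surrogates (tension drivers), and the
#' closed-loop circulation, emitting the twenty pressure-volume features.
#'
#' @param bcl basic cycle length (ms).
#' @return list with \code{name}, \code{space}, \code{fn} as in
#'   \code{\link{forward_model}}.
#' @export
composite_model <- function(bcl = 854) {
  eik <- eikonal_model()
  space <- parameter_space(list(
    param_def("CV_f_v", "hm-constrained", bounds = c(0.3, 1.2),
              unit = "mm/ms", submodel = "tissue-ep"),
    param_def("k_FEC", "hm-constrained", bounds = c(1, 6),
              submodel = "tissue-ep"),
    param_def("AV_delay", "free", bounds = c(100, 200), unit = "ms",
              submodel = "tissue-ep"),
    param_def("T_ref_v", "hm-constrained", bounds = c(60, 180),
              unit = "kPa", submodel = "ventricular-cell"),
    param_def("ca50_v", "hm-constrained", bounds = c(0.35, 0.9),
              unit = "uM", submodel = "ventricular-cell"),
    param_def("r_s_v", "hm-constrained", bounds = c(0.1, 0.4),
              submodel = "ventricular-cell"),
    param_def("T_ref_a", "hm-constrained", bounds = c(30, 100),
              unit = "kPa", submodel = "atrial-cell"),
    param_def("a_V", "free", bounds = c(0.5, 1.5), unit = "kPa",
              submodel = "passive"),
    param_def("b_t_V", "free", bounds = c(1.5, 4.5), submodel = "passive"),
    param_def("R_sys", "free", bounds = c(1, 4), submodel = "circulation"),
    param_def("R_pulm", "free", bounds = c(1, 4), submodel = "circulation"),
    param_def("k_peri", "free", bounds = c(0.5, 2), unit = "kPa/mm",
              submodel = "boundary")))
  out_names <- names(pv_features(run_beats(build_circuit(
    circ_params(bcl = bcl)))))
  fn <- rowwise_simulator(function(x) {
    f <- build_velocity_field(eik$grid, cv_f_v = x["CV_f_v"],
                              cv_f_a = 0.7, k_fec = x["k_FEC"], k_bb = 3)
    src <- data.frame(node = c(attr(eik$grid, "atrial_site"),
                               attr(eik$grid, "ventricular_site")),
                      t0 = c(0, x["AV_delay"]))
    m <- solve_eikonal(eik$grid, f, src)
    tat_v <- total_activation_time(m, c("ventricular-myo", "FEC"), eik$grid)
    tat_a <- total_activation_time(m, c("atrial-myo", "BB"), eik$grid)
    drv_v <- simulate_tension(simulate_calcium(calcium_params(), bcl, dt = 0.1),
                              land_params(T_ref = x["T_ref_v"],
                                          ca50 = x["ca50_v"],
                                          r_s = x["r_s_v"]))
    drv_a <- simulate_tension(
      simulate_calcium(calcium_params(tau_decay = 45), bcl, dt = 0.1),
      land_params(T_ref = x["T_ref_a"]))
    pars <- circ_params(R_sys = x["R_sys"], R_pulm = x["R_pulm"],
                        k_peri = x["k_peri"], av_delay = x["AV_delay"],
                        bcl = bcl)
    cpas <- default_chamber_passive(pars, a_V = x["a_V"],
                                    b_t_V = x["b_t_V"])
    act <- list(LV = list(onset = x[["AV_delay"]], tat = tat_v),
                RV = list(onset = x[["AV_delay"]], tat = tat_v),
                LA = list(onset = 0, tat = tat_a),
                RA = list(onset = 0, tat = tat_a))
    run <- run_beats(build_circuit(pars, cpas,
                                   list(LV = drv_v, RV = drv_v,
                                        LA = drv_a, RA = drv_a), act))
    if (!run$success) stop("failed run")
    pv_features(run)
  }, out_names)
  list(name = "composite", space = space, fn = fn)
}

#' Run one sub-model analysis stage
#'
#' The per-sub-model workflow: Latin hypercube design, simulator
#' evaluation (failed rows excluded from training), per-output emulator
#' fitting, 5-fold cross-validation, Sobol total-effect analysis with
#' posterior averaging, ranking with 90% retention, and optionally
#' history-matching waves against targets. A stage whose mean
#' cross-validation R-squared falls below 0.5 on any output is flagged
#' and the pipeline continues with a warning.
#'
#' @param model a \code{\link{forward_model}} entry (or compatible list
#'   with \code{name}, \code{space}, \code{fn}).
#' @param n_train training design size.
#' @param seed integer seed.
#' @param n_base_gsa Saltelli base size for the stage GSA.
#' @param n_draws posterior draws for the GSA.
#' @param threshold retention threshold.
#' @param targets optional \code{\link{hm_targets}} enabling HM waves.
#' @param hm_waves number of waves when targets are given.
#' @param n_test HM test cloud size.
#' @param I_th implausibility threshold.
#' @param cv_folds cross-validation folds.
#' @param ... passed to \code{\link{gpe}}.
#' @return object of class \code{"stage_report"}.
#' @export
run_submodel_stage <- function(model, n_train = 80, seed = 1,
                               n_base_gsa = 256, n_draws = 30,
                               threshold = 0.9, targets = NULL,
                               hm_waves = 2, n_test = 2000, I_th = 3,
                               cv_folds = 5, ...) {
  space <- model$space
  design <- latin_hypercube(space, n_train, seed)
  Y <- model$fn(unclass(design))
  success <- apply(is.finite(Y), 1, all)
  if (sum(success) < space$D + 2)
    stop(sprintf("stage %s: only %d successful runs for D = %d",
                 model$name, sum(success), space$D))
  Xtr <- unclass(design)[success, , drop = FALSE]
  attr(Xtr, "space") <- space
  outs <- colnames(Y)
  models <- lapply(stats::setNames(outs, outs), function(o)
    gpe(Xtr, Y[success, o], seed = seed, ...))
  cv <- lapply(stats::setNames(outs, outs), function(o)
    cross_validate(Xtr, Y[success, o], k_folds = cv_folds, seed = seed, ...))
  mean_r2 <- vapply(cv, `[[`, numeric(1), "mean_r2")
  flagged <- any(mean_r2 < 0.5)
  if (flagged)
    warning(sprintf("stage %s: emulator inadequate (mean R^2 < 0.5) for: %s",
                    model$name,
                    paste(outs[mean_r2 < 0.5], collapse = ", ")))
  sobol <- sobol_total_effects(models, space, n_base = n_base_gsa,
                               n_draws = n_draws, seed = seed)
  ranking <- rank_and_retain(sobol, threshold)
  hm <- NULL
  if (!is.null(targets) && hm_waves > 0) {
    st <- hm_wave(space, model$fn, targets, I_th = I_th, n_test = n_test,
                  n_simul = max(4 * space$D, space$D + 2), seed = seed, ...)
    hm <- list(st)
    for (w in seq_len(hm_waves - 1)) {
      if (st$exhausted) break
      st <- hm_wave(st, model$fn, targets, I_th = I_th, n_test = n_test,
                    seed = seed + w, ...)
      hm <- c(hm, list(st))
    }
  }
  structure(list(name = model$name, space = space, design = design,
                 outputs = Y, success = success, models = models, cv = cv,
                 flagged = flagged, sobol = sobol, ranking = ranking,
                 hm = hm, seed = seed),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("Stage '%s': %d/%d successful runs, D = %d%s\n", x$name,
              sum(x$success), length(x$success), x$space$D,
              if (x$flagged) " [FLAGGED: emulator inadequate]" else ""))
  r2 <- vapply(x$cv, `[[`, numeric(1), "mean_r2")
  ise <- vapply(x$cv, `[[`, numeric(1), "mean_ise")
  print(data.frame(output = names(r2), mean_r2 = round(r2, 3),
                   mean_ise = round(ise, 1)), row.names = FALSE)
  cat(sprintf("Retained %d/%d parameters: %s\n",
              length(x$ranking$retained), x$space$D,
              paste(x$ranking$retained, collapse = ", ")))
  if (!is.null(x$hm))
    for (st in x$hm) print(st$diagnostics)
  invisible(x)
}

#' Pipeline configuration
#'
#' Sizes and seeds for the hierarchical analysis. The \code{"desk"} preset
#' uses design sizes a single CPU handles in minutes; the \code{"paper"}
#' preset documents the cluster-scale constants (500 training samples,
#' 100000-point test clouds, base screening sequence of 2000).
#'
#' @param scale \code{"desk"} or \code{"paper"}.
#' @param seed master integer seed.
#' @param threshold retention threshold (default 0.90).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(scale = c("desk", "paper"), seed = 1,
                            threshold = 0.9) {
  scale <- match.arg(scale)
  sizes <- if (scale == "desk") {
    list(n_train_stage = 70, n_train_final = 120, n_test_hm = 6000,
         n_base_gsa = 256, n_base_screen = 500, n_required_screen = 400,
         n_draws = 20, hm_waves = 2)
  } else {
    list(n_train_stage = 200, n_train_final = 500, n_test_hm = 100000,
         n_base_gsa = 2000, n_base_screen = 2000, n_required_screen = 2000,
         n_draws = 1000, hm_waves = 3)
  }
  structure(c(list(scale = scale, seed = seed, threshold = threshold),
              sizes), class = "pipeline_config")
}

#' Run the hierarchical whole-organ analysis
#'
#' Chains the sub-model stages into the whole-organ sensitivity analysis:
#' (1) per-sub-model emulation, cross-validation, GSA and retention, with
#' history-matching waves for the activation and ventricular-cell stages
#' against self-consistent targets; (2) intersection of the plausible
#' clouds with a Latin hypercube over the unconstrained block; (3)
#' space-filling subsampling of the joint plausible region; (4) the
#' composite forward chain evaluated on the final design (failures
#' counted, excluded from training); (5) per-output emulators with
#' cross-validation; (6) a screened Sobol GSA whose samples must pass
#' every sub-model constraint; and (7) ranking, retention and the signed
#' effect matrix.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{"analysis_report"}.
#' @export
run_full_analysis <- function(config = pipeline_config()) {
  seed <- config$seed
  comp <- composite_model()

  # --- sub-model stages ------------------------------------------------
  eik <- eikonal_model()
  vcell <- cell_model("ventricular")
  # self-consistent targets from a known plausible point
  eik_true <- scale_from_unit(eik$space,
                              matrix(0.5, 1, eik$space$D))
  eik_tgt_y <- eik$fn(eik_true)
  eik_targets <- hm_targets(colnames(eik_tgt_y), as.numeric(eik_tgt_y),
                            pmax(0.05 * abs(as.numeric(eik_tgt_y)), 1))
  vc_true <- scale_from_unit(vcell$space, matrix(0.5, 1, vcell$space$D))
  vc_tgt_y <- vcell$fn(vc_true)
  vc_targets <- hm_targets(colnames(vc_tgt_y), as.numeric(vc_tgt_y),
                           pmax(0.05 * abs(as.numeric(vc_tgt_y)), 0.01))

  stages <- list(
    eikonal = run_submodel_stage(eik, n_train = config$n_train_stage,
                                 seed = seed, n_base_gsa = config$n_base_gsa,
                                 n_draws = config$n_draws,
                                 threshold = config$threshold,
                                 targets = eik_targets,
                                 hm_waves = config$hm_waves,
                                 n_test = config$n_test_hm,
                                 n_restarts = 2),
    ventricular_cell = run_submodel_stage(
      vcell, n_train = config$n_train_stage, seed = seed + 1,
      n_base_gsa = config$n_base_gsa, n_draws = config$n_draws,
      threshold = config$threshold, targets = vc_targets,
      hm_waves = config$hm_waves, n_test = config$n_test_hm,
      n_restarts = 2),
    passive = run_submodel_stage(passive_model(),
                                 n_train = config$n_train_stage,
                                 seed = seed + 2,
                                 n_base_gsa = config$n_base_gsa,
                                 n_draws = config$n_draws,
                                 threshold = config$threshold,
                                 targets = NULL, n_restarts = 2),
    circulation = run_submodel_stage(circulation_model(),
                                     n_train = config$n_train_stage,
                                     seed = seed + 3,
                                     n_base_gsa = config$n_base_gsa,
                                     n_draws = config$n_draws,
                                     threshold = config$threshold,
                                     targets = NULL, n_restarts = 2))

  # --- joint plausible design -----------------------------------------
  # plausible clouds over the constrained blocks shared with the
  # composite space, plus an LHS block over the rest
  comp_names <- comp$space$free
  eik_last <- stages$eikonal$hm[[length(stages$eikonal$hm)]]
  eik_cloud <- unclass(eik_last$cloud)[eik_last$plausible,
                                       intersect(colnames(eik_last$cloud),
                                                 comp_names),
                                       drop = FALSE]
  vc_last <- stages$ventricular_cell$hm[[length(stages$ventricular_cell$hm)]]
  vc_cloud <- unclass(vc_last$cloud)[vc_last$plausible, , drop = FALSE]
  vc_cloud <- vc_cloud[, intersect(colnames(vc_cloud),
                                   c("T_ref", "ca50", "r_s")), drop = FALSE]
  colnames(vc_cloud) <- paste0(colnames(vc_cloud), "_v")
  rest <- setdiff(comp_names, c(colnames(eik_cloud), colnames(vc_cloud)))
  rest_space <- parameter_space(lapply(rest, function(nm) {
    b <- comp$space$bounds[nm, ]
    param_def(nm, "free", bounds = b)
  }))
  # clouds are resampled with replacement up to twice the final design so
  # a small plausible region does not truncate the joint sample
  n_cloud <- 2L * config$n_train_final
  resample <- function(cl, s) cl[with_seed(s, sample.int(nrow(cl), n_cloud,
                                                         replace = TRUE)), ,
                                 drop = FALSE]
  eik_cloud <- resample(eik_cloud, seed + 9)
  vc_cloud <- resample(vc_cloud, seed + 10)
  rest_lhs <- latin_hypercube(rest_space, n_cloud, seed + 11)
  joint <- intersect_regions(list(eik_cloud, vc_cloud),
                             extra_lhs = unclass(rest_lhs), seed = seed + 12)
  joint <- joint[, comp_names, drop = FALSE]
  final_design <- subsample_space_filling(joint,
                                          min(config$n_train_final,
                                              nrow(joint)),
                                          seed + 13, space = comp$space)

  # --- composite runs and final emulation -----------------------------
  Y <- comp$fn(unclass(final_design))
  success <- apply(is.finite(Y), 1, all)
  if (sum(success) < comp$space$D + 2)
    stop("fewer than D + 2 successful composite runs")
  Xtr <- unclass(final_design)[success, , drop = FALSE]
  attr(Xtr, "space") <- comp$space
  outs <- colnames(Y)
  models <- lapply(stats::setNames(outs, outs), function(o)
    gpe(Xtr, Y[success, o], seed = seed, n_restarts = 2))
  cv <- lapply(stats::setNames(outs, outs), function(o)
    cross_validate(Xtr, Y[success, o], k_folds = 5, seed = seed,
                   n_restarts = 2))

  # --- screened GSA ----------------------------------------------------
  sobol <- screened_sobol(models, comp$space,
                          stages = list(eikonal = eik_last,
                                        ventricular_cell = vc_last),
                          n_base = config$n_base_screen,
                          n_draws = config$n_draws, I_th = 3,
                          seed = seed + 20)
  ranking <- rank_and_retain(sobol, config$threshold)
  signed <- signed_effects(sobol, models)

  retained_counts <- c(
    vapply(stages, function(s) length(s$ranking$retained), integer(1)),
    composite = length(ranking$retained))

  structure(list(stages = stages, final_design = final_design,
                 outputs = Y, success = success, models = models, cv = cv,
                 sobol = sobol, ranking = ranking, signed = signed,
                 retained_counts = retained_counts, config = config),
            class = "analysis_report")
}

# Saltelli GSA over a design screened through sub-model plausibility:
# columns covered by a constrained stage are sampled from that stage's
# plausible cloud, the rest from the box, so every GSA sample respects
# the sub-model constraints while preserving the Saltelli structure.
screened_sobol <- function(models, space, stages, n_base, n_draws, I_th,
                           seed) {
  D <- space$D
  # build A/B half-matrices by drawing block-wise from plausible clouds
  draw_rows <- function(n, s) {
    out <- matrix(NA_real_, n, D, dimnames = list(NULL, space$free))
    used <- character(0)
    k <- 0L
    for (st in stages) {
      cloud <- unclass(st$cloud)[st$plausible, , drop = FALSE]
      cols <- intersect(colnames(cloud), space$free)
      remap <- cols
      if (!length(cols)) {
        # composite names carry a _v suffix for the ventricular block
        cols <- intersect(paste0(colnames(cloud), "_v"), space$free)
        remap <- sub("_v$", "", cols)
      }
      if (!length(cols)) next
      idx <- with_seed(seed + 100 + k,
                       sample.int(nrow(cloud), n, replace = TRUE))
      out[, cols] <- cloud[idx, remap, drop = FALSE]
      used <- c(used, cols)
      k <- k + 1L
    }
    rest <- setdiff(space$free, used)
    if (length(rest)) {
      rs <- parameter_space(lapply(rest, function(nm)
        param_def(nm, "free", bounds = space$bounds[nm, ])))
      out[, rest] <- unclass(latin_hypercube(rs, n, seed + 200 + s))
    }
    out
  }
  A <- draw_rows(n_base, 1)
  B <- draw_rows(n_base, 2)
  blocks <- vector("list", D + 2L)
  blocks[[1]] <- A; blocks[[2]] <- B
  for (i in seq_len(D)) {
    ABi <- A; ABi[, i] <- B[, i]; blocks[[i + 2L]] <- ABi
  }
  design <- do.call(rbind, blocks)
  design <- new_design(design, space, "saltelli", seed)
  attr(design, "n_base") <- as.integer(n_base)
  sobol_total_effects(models, space, n_base = n_base, n_draws = n_draws,
                      seed = seed, design = design)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Hierarchical whole-organ sensitivity analysis\n")
  cat(sprintf("Final design: %d points, %d successful composite runs\n",
              nrow(x$final_design), sum(x$success)))
  cat("Retained parameters per stage:\n")
  print(x$retained_counts)
  cat(sprintf("Composite retained set (%d): %s\n",
              length(x$ranking$retained),
              paste(x$ranking$retained, collapse = ", ")))
  invisible(x)
}

#' Write analysis artifacts to a directory
#'
#' Persists the normalized total-effect heatmap matrix, the signed
#' effects, per-output CV scores, per-output top-parameter bar data
#' (truncated at 10 parameters or the 90% set) and a JSON run manifest
#' (seeds, sizes, config hash).
#'
#' @param analysis an \code{\link{run_full_analysis}} report.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
report <- function(analysis, outdir) {
  stopifnot(inherits(analysis, "analysis_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  norm <- normalize_effects(analysis$sobol)
  utils::write.csv(norm, file.path(outdir, "total_effects_normalized.csv"))
  utils::write.csv(analysis$sobol$total_effects,
                   file.path(outdir, "total_effects_raw.csv"))
  utils::write.csv(analysis$signed, file.path(outdir, "signed_effects.csv"))
  r2 <- vapply(analysis$cv, `[[`, numeric(1), "mean_r2")
  ise <- vapply(analysis$cv, `[[`, numeric(1), "mean_ise")
  utils::write.csv(data.frame(output = names(r2), mean_r2 = r2,
                              mean_ise = ise),
                   file.path(outdir, "cv_scores.csv"), row.names = FALSE)
  bars <- lapply(colnames(analysis$signed), function(o) {
    s <- analysis$signed[, o]
    ord <- order(-abs(s))
    share <- abs(s[ord]) / max(sum(abs(s)), 1e-300)
    keep <- min(10, max(which(cumsum(share) < 0.9), 0) + 1, length(s))
    data.frame(output = o, parameter = names(s)[ord][seq_len(keep)],
               signed_effect = s[ord][seq_len(keep)])
  })
  utils::write.csv(do.call(rbind, bars), file.path(outdir, "bars.csv"),
                   row.names = FALSE)
  cfg <- analysis$config
  manifest <- list(
    scale = cfg$scale, seed = cfg$seed, threshold = cfg$threshold,
    n_train_final = cfg$n_train_final,
    n_failed_runs = sum(!analysis$success),
    retained_counts = as.list(analysis$retained_counts),
    config_hash = sum(utf8ToInt(paste(unlist(cfg), collapse = ","))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Generate the default fixtures
#'
#' Writes the desk-scale fixtures to a directory: the two-slab labelled
#' grid (CSV: node, x, y, label, fibre components), the full simulator
#' parameter table (YAML), and self-consistent history-matching targets
#' (CSV) produced by simulating a known "true" parameter point of the
#' activation and ventricular-cell models and attaching a 5% standard
#' deviation — enabling closed-loop parameter-recovery experiments.
#'
#' @param outdir output directory.
#' @param seed integer seed (the true point is drawn from a seeded
#'   design).
#' @return invisibly, a list with the true points and target tables.
#' @export
generate_fixtures <- function(outdir, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  grid <- two_slab_geometry()
  xyz <- node_coords(grid)
  utils::write.csv(data.frame(node = seq_len(grid$n), x_mm = xyz[, 1],
                              y_mm = xyz[, 2], label = grid$labels,
                              fx = grid$fibres[, 1], fy = grid$fibres[, 2]),
                   file.path(outdir, "two_slab_grid.csv"),
                   row.names = FALSE)
  src <- system.file("extdata", "parameter_table.yaml",
                     package = "cardioemu")
  file.copy(src, file.path(outdir, "parameter_table.yaml"),
            overwrite = TRUE)
  eik <- eikonal_model(); vcell <- cell_model("ventricular")
  true_eik <- unclass(latin_hypercube(eik$space, 1, seed))
  true_vc <- unclass(latin_hypercube(vcell$space, 1, seed + 1))
  y_eik <- eik$fn(true_eik); y_vc <- vcell$fn(true_vc)
  tg <- rbind(
    data.frame(submodel = "eikonal", output = colnames(y_eik),
               mu = as.numeric(y_eik),
               sigma = pmax(0.05 * abs(as.numeric(y_eik)), 1)),
    data.frame(submodel = "ventricular_cell", output = colnames(y_vc),
               mu = as.numeric(y_vc),
               sigma = pmax(0.05 * abs(as.numeric(y_vc)), 0.01)))
  utils::write.csv(tg, file.path(outdir, "targets.csv"), row.names = FALSE)
  utils::write.csv(data.frame(parameter = c(colnames(true_eik),
                                            colnames(true_vc)),
                              submodel = c(rep("eikonal", ncol(true_eik)),
                                           rep("ventricular_cell",
                                               ncol(true_vc))),
                              value = c(as.numeric(true_eik),
                                        as.numeric(true_vc))),
                   file.path(outdir, "true_point.csv"), row.names = FALSE)
  invisible(list(true_eikonal = true_eik, true_cell = true_vc,
                 targets = tg))
}
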
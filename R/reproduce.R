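# Configuration schema and the one-call reproduction of the simulation
# figure pipeline: solve -> profile -> calibrate -> swirl classification.

#' Default run configuration
#'
#' All defaults equal the calibrated model parameters: geometry (Z0 = 8.2,
#' R0 = 35, r1 = 15, rho2 = 22 µm, alpha = 7 deg), activity (lambda1 =
#' 150/R0, lambda2 = 20/R0 per µm, beta = 1.7 alpha, xi = 0.06 R0, xi3 =
#' 0.7 R0 µm, Z0' = 1.5 Z0), chiral activity zeta = 0.004, and the
#' experimental peak speed 1e-2 µm/s used for dimensional calibration.
#'
#' @return A nested list of class `run_config` with components `geometry`,
#'   `activity`, `solver`, `calibration`, `analysis`.
#' @export
default_run_config <- function() {
  structure(list(
    geometry = list(z0_um = 8.2, r0_um = 35.0, r1_um = 15.0, rho2_um = 22.0,
                    alpha_deg = 7.0),
    activity = list(lambda1_per_um = 150 / 35, lambda2_per_um = 20 / 35,
                    beta_scale = 1.7, xi_um = 0.06 * 35, xi3_um = 0.7 * 35,
                    z0p_um = 1.5 * 8.2),
    solver = list(zeta = 0.004, h_um = 0.35),
    calibration = list(exp_peak_speed_um_s = 1e-2),
    analysis = list(n_rho_profile = 175, ring_threshold = 0.8)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (sec in names(base)) {
    if (!is.null(cfg[[sec]])) base[[sec]] <- utils::modifyList(base[[sec]], cfg[[sec]])
  }
  base
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_objects <- function(config) {
  g <- config$geometry
  shape <- cell_shape(z0_um = g$z0_um, r0_um = g$r0_um, r1_um = g$r1_um,
                      rho2_um = g$rho2_um, alpha_rad = g$alpha_deg * pi / 180)
  a <- config$activity
  act <- activity_params(shape,
                         lambda1_per_um = a$lambda1_per_um,
                         lambda2_per_um = a$lambda2_per_um,
                         beta_rad = a$beta_scale * shape$alpha_rad,
                         xi_um = a$xi_um, xi3_um = a$xi3_um,
                         z0p_um = a$z0p_um)
  list(shape = shape, act = act,
       solver = solver_config(zeta = config$solver$zeta,
                              h_um = config$solver$h_um))
}

#' Run the full simulation reproduction pipeline
#'
#' Solves the active chiral Stokes problem with the configured parameters,
#' computes the z-averaged clockwise angular-velocity profile, the ring
#' inner radius, the dimensional calibration, and the dorsal/ventral swirl
#' classifications, and collects everything in a report list (JSON-ready).
#'
#' @param config A [default_run_config()]-style configuration.
#' @param out_dir Optional output directory; if given, writes `report.json`,
#'   `profile.csv` and `fields.vtk` there.
#' @return A list of class `reproduction_report` with elements `solution`,
#'   `profile`, and `report` (named scalars: peak speeds, calibration
#'   scales, peak angular velocity and location, handedness labels, checks).
#' @export
run_reproduction <- function(config = default_run_config(), out_dir = NULL) {
  obj <- config_objects(config)
  sol <- solve_flow(obj$shape, obj$act, obj$solver)
  prof <- angular_velocity_profile(
    sol, exp_peak_speed_um_s = config$calibration$exp_peak_speed_um_s,
    n_rho = config$analysis$n_rho_profile)
  cal <- attr(prof, "calibration")
  peak <- attr(prof, "peak")
  dors <- surface_swirl(sol, "dorsal")
  vent <- surface_swirl(sol, "ventral")
  interior <- sol$vphi[sol$vphi != 0]
  report <- list(
    zeta = sol$zeta,
    peak_vphi_nondim = sol$diagnostics$peak_vphi,
    peak_meridional_nondim = sol$diagnostics$peak_meridional,
    velocity_scale_um_s = cal$velocity_scale_um_s,
    time_scale_s = cal$time_scale_s,
    rho_a_um = attr(prof, "rho_a_um"),
    peak_omega_deg_hr = peak$peak_deg_hr,
    peak_location_scaled = peak$peak_location_scaled,
    dorsal_pattern = paste(dors$handedness, dors$radial_sense, sep = ", "),
    ventral_pattern = paste(vent$handedness, vent$radial_sense, sep = ", "),
    vphi_nonpositive = all(sol$vphi <= 0),
    div_discrete_rel = sol$diagnostics$div_discrete_rel,
    n_p2 = sol$diagnostics$n_p2
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(prof), file.path(out_dir, "profile.csv"),
                     row.names = FALSE)
    write_flow_vtk(sol, file.path(out_dir, "fields.vtk"))
  }
  structure(list(solution = sol, profile = prof, report = report),
            class = "reproduction_report")
}

#' @method print reproduction_report
#' @export
print.reproduction_report <- function(x, ...) {
  r <- x$report
  cat("<reproduction_report>\n")
  cat(sprintf("  peak |v_phi| = %.3g, peak meridional = %.3g (non-dim.)\n",
              r$peak_vphi_nondim, r$peak_meridional_nondim))
  cat(sprintf("  velocity scale = %.3g um/s, time scale = %.3g s\n",
              r$velocity_scale_um_s, r$time_scale_s))
  cat(sprintf("  ring inner radius rho_a = %.3g um\n", r$rho_a_um))
  cat(sprintf("  peak angular velocity = %.3g deg/hr at rho/rho_a = %.3g\n",
              r$peak_omega_deg_hr, r$peak_location_scaled))
  cat(sprintf("  dorsal: %s; ventral: %s\n", r$dorsal_pattern, r$ventral_pattern))
  cat(sprintf("  v_phi <= 0 everywhere: %s\n", r$vphi_nonpositive))
  invisible(x)
}
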
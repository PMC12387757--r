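# Post-processing of flow solutions into the rotation diagnostics used for
# the cell: z-averaged angular-velocity profiles, actomyosin-ring inner
# radius, dimensional calibration, and surface swirl classification.

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch).
gauss_legendre01 <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2
  w <- e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' z-averaged clockwise angular-velocity profile
#'
#' For each radius the angular velocity `-v_phi / rho` (clockwise viewed
#' from above is positive) is averaged over the local cell height with
#' uniform weight (a per-column average, not a volume average), using
#' Gauss-Legendre quadrature along z.
#'
#' @param sol A [solve_flow()] solution, or a function `v_phi(rho_um, z_um)`
#'   returning the non-dimensional azimuthal velocity (then `shape` must be
#'   given).
#' @param n_rho Number of radial grid points.
#' @param n_quad_z Gauss-Legendre points per column.
#' @param shape A [cell_shape()]; defaults to the solution's shape.
#' @return A tibble with `rho_um` and non-dimensional `omega_cw`, of class
#'   `angular_velocity_profile`.
#' @export
z_average_omega <- function(sol, n_rho = 175, n_quad_z = 24, shape = NULL) {
  if (inherits(sol, "flow_solution")) {
    shape <- sol$shape
    vphi_fun <- function(rho_um, z_um) {
      eval_p2_field(sol$mesh, sol$p2, sol$vphi,
                    rho_um / shape$r0_um, z_um / shape$r0_um)
    }
  } else {
    stopifnot(is.function(sol), inherits(shape, "cell_shape"))
    vphi_fun <- sol
  }
  gl <- gauss_legendre01(n_quad_z)
  rho <- seq(shape$r0_um / n_rho, shape$r0_um * (1 - 1 / n_rho),
             length.out = n_rho - 1)
  h <- dorsal_height(rho, shape)
  omega <- vapply(seq_along(rho), function(i) {
    z <- gl$x * h[i]
    v <- vphi_fun(rep(rho[i], n_quad_z), z)
    sum(gl$w * (-v / (rho[i] / shape$r0_um)))
  }, numeric(1))
  out <- tibble::tibble(rho_um = rho, omega_cw = omega)
  class(out) <- c("angular_velocity_profile", class(out))
  attr(out, "shape") <- shape
  out
}

#' Inner radius of the actomyosin ring
#'
#' The smallest radius at which the order parameter reaches `threshold`
#' anywhere over the cell height (max over z per radius), refined by
#' bisection to `tol_um`.
#'
#' @param shape A [cell_shape()].
#' @param act An [activity_params()].
#' @param threshold S threshold, default 0.8.
#' @param n_scan Radial scan resolution.
#' @param n_z z samples per radius for the max.
#' @param tol_um Bisection tolerance (µm).
#' @return The ring inner radius rho_a in µm.
#' @export
ring_inner_radius <- function(shape, act, threshold = 0.8, n_scan = 400,
                              n_z = 200, tol_um = 1e-3) {
  max_s <- function(rho) {
    h <- dorsal_height(rho, shape)
    z <- seq(0, h, length.out = n_z)
    max(order_parameter(rep(rho, n_z), z, shape, act))
  }
  grid <- seq(0, shape$r0_um, length.out = n_scan + 1)
  vals <- vapply(grid, max_s, numeric(1))
  hit <- which(vals >= threshold)
  if (!length(hit)) {
    stop(sprintf("order parameter never reaches the threshold %.3g", threshold))
  }
  i <- hit[1]
  if (i == 1) return(grid[1])
  lo <- grid[i - 1]; hi <- grid[i]
  while (hi - lo > tol_um) {
    mid <- (lo + hi) / 2
    if (max_s(mid) >= threshold) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Peak of a radial profile by parabolic interpolation
#'
#' Locates the discrete maximum of `omega_cw` and refines it with a parabola
#' through the three surrounding samples. If the maximum falls on the first
#' or last grid point the discrete value is returned with `at_boundary =
#' TRUE` and no interpolation.
#'
#' @param profile An `angular_velocity_profile` tibble (or any tibble with
#'   `rho_um` and a value column).
#' @param rho_a_um Optional ring inner radius; when given the peak location
#'   is also reported as `rho_peak / rho_a`.
#' @param value Name of the value column, default `"omega_cw"`.
#' @return A list with `peak_value`, `peak_rho_um`, `peak_location_scaled`
#'   (NA without `rho_a_um`), and `at_boundary`.
#' @export
peak_of_profile <- function(profile, rho_a_um = NULL, value = "omega_cw") {
  x <- profile$rho_um
  y <- profile[[value]]
  stopifnot(length(x) >= 3, !is.unsorted(x))
  i <- which.max(y)
  if (i == 1 || i == length(y)) {
    return(list(peak_value = y[i], peak_rho_um = x[i],
                peak_location_scaled = if (is.null(rho_a_um)) NA_real_ else x[i] / rho_a_um,
                at_boundary = TRUE))
  }
  # vertex of the parabola through the three points around the maximum
  x0 <- x[i - 1]; x1 <- x[i]; x2 <- x[i + 1]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  d1 <- (y1 - y0) / (x1 - x0)
  d2 <- (y2 - y1) / (x2 - x1)
  a <- (d2 - d1) / (x2 - x0)
  xv <- if (abs(a) < 1e-300) x1 else (x0 + x1) / 2 - d1 / (2 * a)
  # Newton form through (x0,y0),(x1,y1),(x2,y2)
  yv <- y0 + d1 * (xv - x0) + a * (xv - x0) * (xv - x1)
  list(peak_value = yv, peak_rho_um = xv,
       peak_location_scaled = if (is.null(rho_a_um)) NA_real_ else xv / rho_a_um,
       at_boundary = FALSE)
}

#' Dimensional calibration of the non-dimensional flow
#'
#' Velocities are simulated in units of the active velocity scale; matching
#' the simulated peak speed against an experimentally measured peak speed
#' fixes that scale and hence the time scale used to express angular
#' velocities in degrees per hour.
#'
#' @param sim_peak_speed Peak non-dimensional speed of the simulation.
#' @param exp_peak_speed_um_s Experimental peak speed (µm/s); default 1e-2,
#'   the upper end of the measured range, the value consistent with a
#'   50 µm/s velocity scale.
#' @param r0_um Cell radius (µm).
#' @return An object of class `dimensional_calibration` with
#'   `velocity_scale_um_s` and `time_scale_s`.
#' @examples
#' calibrate(2e-4, 1e-2, 35) # velocity scale 50 um/s, time scale 0.7 s
#' @export
calibrate <- function(sim_peak_speed, exp_peak_speed_um_s = 1e-2, r0_um = 35) {
  stopifnot(is_pos_scalar(exp_peak_speed_um_s), is_pos_scalar(r0_um))
  if (!is_pos_scalar(sim_peak_speed)) {
    stop("sim_peak_speed must be a positive number")
  }
  vs <- exp_peak_speed_um_s / sim_peak_speed
  structure(list(sim_peak_speed = sim_peak_speed,
                 exp_peak_speed_um_s = exp_peak_speed_um_s,
                 r0_um = r0_um,
                 velocity_scale_um_s = vs,
                 time_scale_s = r0_um / vs),
            class = "dimensional_calibration")
}

#' @method print dimensional_calibration
#' @export
print.dimensional_calibration <- function(x, ...) {
  cat(sprintf("<dimensional_calibration> velocity scale %.4g um/s, time scale %.4g s\n",
              x$velocity_scale_um_s, x$time_scale_s))
  invisible(x)
}

#' Convert a non-dimensional angular velocity to degrees per hour
#'
#' @param omega Non-dimensional angular velocity (per non-dimensional time).
#' @param calibration A [calibrate()] object.
#' @return Angular velocity in degrees/hr.
#' @export
omega_deg_per_hr <- function(omega, calibration) {
  stopifnot(inherits(calibration, "dimensional_calibration"))
  omega / calibration$time_scale_s * (180 / pi) * 3600
}

#' Full angular-velocity profile with calibration and ring rescaling
#'
#' Convenience composition: z-averages the azimuthal flow, finds the ring
#' inner radius from the activity field, calibrates against an experimental
#' peak speed, and reports the peak.
#'
#' @param sol A `flow_solution`.
#' @param exp_peak_speed_um_s Experimental peak speed for calibration (µm/s).
#' @inheritParams z_average_omega
#' @return An `angular_velocity_profile` tibble with columns `rho_um`,
#'   `rho_scaled`, `omega_cw` (non-dimensional) and `omega_deg_hr`, and
#'   attributes `rho_a_um`, `calibration`, `peak`.
#' @export
angular_velocity_profile <- function(sol, exp_peak_speed_um_s = 1e-2,
                                     n_rho = 175, n_quad_z = 24) {
  stopifnot(inherits(sol, "flow_solution"))
  prof <- z_average_omega(sol, n_rho = n_rho, n_quad_z = n_quad_z)
  rho_a <- ring_inner_radius(sol$shape, sol$act)
  # The experimental peak speed comes from planar imaging of the azimuthal
  # flow, so the matching simulated quantity is the peak azimuthal speed.
  cal <- calibrate(sol$diagnostics$peak_vphi, exp_peak_speed_um_s,
                   sol$shape$r0_um)
  prof$rho_scaled <- prof$rho_um / rho_a
  prof$omega_deg_hr <- omega_deg_per_hr(prof$omega_cw, cal)
  peak <- peak_of_profile(prof, rho_a_um = rho_a)
  peak$peak_deg_hr <- omega_deg_per_hr(peak$peak_value, cal)
  attr(prof, "rho_a_um") <- rho_a
  attr(prof, "calibration") <- cal
  attr(prof, "peak") <- peak
  prof
}

#' Classify the swirl pattern next to a boundary layer
#'
#' Samples the flow on a thin layer adjacent to the dorsal or ventral
#' boundary and classifies the radial sense by the sign of the mean radial
#' velocity and the rotation sense by the sign of the mean azimuthal
#' velocity (negative = clockwise viewed from above). The handedness of the
#' spiral streamline pattern seen from above combines both: an inward
#' clockwise or outward counter-clockwise pattern is sinistral, the two
#' opposite combinations dextral.
#'
#' @param sol A `flow_solution`.
#' @param side `"dorsal"` or `"ventral"`.
#' @param offset_frac Layer offset from the boundary as a fraction of the
#'   local cell height.
#' @param noise_floor Relative magnitude (vs the solution peak speed) below
#'   which a mean is considered indeterminate.
#' @return A one-row tibble: `side`, `radial_sense`, `rotation_sense`,
#'   `handedness`, `mean_v_rho`, `mean_v_phi`.
#' @export
surface_swirl <- function(sol, side = c("dorsal", "ventral"),
                          offset_frac = 0.1, noise_floor = 1e-4) {
  side <- match.arg(side)
  shape <- sol$shape
  rho <- seq(shape$r0_um * 0.02, shape$r0_um * 0.98, length.out = 120)
  h <- dorsal_height(rho, shape)
  z <- if (side == "dorsal") h * (1 - offset_frac) else h * offset_frac
  fv <- flow_velocity(sol, rho, z)
  m_rho <- mean(fv$v_rho, na.rm = TRUE)
  m_phi <- mean(fv$v_phi, na.rm = TRUE)
  floor_abs <- noise_floor * max(sol$diagnostics$peak_speed, 1e-300)
  radial <- if (abs(m_rho) <= floor_abs) "indeterminate"
            else if (m_rho < 0) "inward" else "outward"
  rotation <- if (abs(m_phi) <= floor_abs) "indeterminate"
              else if (m_phi < 0) "clockwise" else "counterclockwise"
  handed <- if (radial == "indeterminate" || rotation == "indeterminate") {
    "indeterminate"
  } else if ((radial == "inward") == (rotation == "clockwise")) {
    "sinistral"
  } else {
    "dextral"
  }
  tibble::tibble(side = side, radial_sense = radial,
                 rotation_sense = rotation, handedness = handed,
                 mean_v_rho = m_rho, mean_v_phi = m_phi)
}
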
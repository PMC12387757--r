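# Seed-deterministic generators of ground-truth inputs with the statistical
# structure the quantification stages assume: swirl velocity-field series
# (rotation + centripetal inflow with a clockwise bias, circular mask,
# Gaussian velocity noise), rotating two-landmark tracks, simulation
# solutions sampled onto PIV-style grids, and manufactured-solution forcings
# for solver verification.

#' Generate a synthetic swirl velocity-field series
#'
#' Composes a clockwise rotation profile and a radial (by default inward)
#' speed profile into image-convention `(v_x, v_y)` grids with a circular
#' valid mask and i.i.d. Gaussian noise per velocity component, frame and
#' grid point, with standard deviation a fraction of the local speed.
#'
#' @param omega_deg_hr Angular-velocity profile: a constant (deg/hr,
#'   positive clockwise) or a function of radius (µm).
#' @param v_r_um_s Radial-speed profile: constant (µm/s, negative = inward)
#'   or function of radius.
#' @param domain_radius_um Mask radius (µm).
#' @param spacing_um Grid spacing (µm).
#' @param frame_interval_s Time between frames (s).
#' @param n_frames Number of frames.
#' @param noise_sd_frac Noise standard deviation as a fraction of the local
#'   speed.
#' @param center_um Cell centre in the image (µm).
#' @param seed Integer seed; the series is bit-reproducible given the seed.
#' @return A [planar_velocity_field()] tibble; ground-truth parameters are
#'   stored in the `ground_truth` attribute.
#' @examples
#' f <- make_swirl_series(n_frames = 2, seed = 1)
#' head(f)
#' @export
make_swirl_series <- function(omega_deg_hr = 50, v_r_um_s = -0.002,
                              domain_radius_um = 25, spacing_um = 1,
                              frame_interval_s = 14.8, n_frames = 40,
                              noise_sd_frac = 0.1,
                              center_um = c(0, 0), seed = 1L) {
  stopifnot(spacing_um > 0, n_frames >= 1, noise_sd_frac >= 0)
  omega_fun <- if (is.function(omega_deg_hr)) omega_deg_hr else function(r) rep_len(omega_deg_hr, length(r))
  vr_fun <- if (is.function(v_r_um_s)) v_r_um_s else function(r) rep_len(v_r_um_s, length(r))
  g <- seq(-domain_radius_um, domain_radius_um, by = spacing_um)
  grid <- expand.grid(x_um = g + center_um[1], y_um = g + center_um[2])
  x <- grid$x_um - center_um[1]
  y <- grid$y_um - center_um[2]
  r <- sqrt(x^2 + y^2)
  inside <- r <= domain_radius_um
  rad2 <- pi / 180 / 3600                      # deg/hr -> rad/s
  v_cw <- omega_fun(r) * rad2 * r              # clockwise tangential speed, um/s
  v_r <- vr_fun(r)
  safe <- pmax(r, 1e-12)
  vx0 <- v_r * x / safe + v_cw * (-y) / safe
  vy0 <- v_r * y / safe + v_cw * x / safe
  vx0[r == 0] <- 0; vy0[r == 0] <- 0
  speed <- sqrt(vx0^2 + vy0^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  frames <- purrr::map(seq_len(n_frames) - 1L, function(k) {
    nx <- stats::rnorm(length(vx0), 0, noise_sd_frac * speed)
    ny <- stats::rnorm(length(vy0), 0, noise_sd_frac * speed)
    tibble::tibble(time_s = k * frame_interval_s,
                   x_um = grid$x_um, y_um = grid$y_um,
                   vx_um_s = vx0 + nx, vy_um_s = vy0 + ny,
                   valid = inside)
  })
  out <- planar_velocity_field(dplyr::bind_rows(frames), center_um = center_um)
  attr(out, "ground_truth") <- list(omega_deg_hr = omega_deg_hr,
                                    v_r_um_s = v_r_um_s,
                                    noise_sd_frac = noise_sd_frac,
                                    seed = seed)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a rotating two-landmark track
#'
#' Two points at fixed separation rotating clockwise (on screen) about a
#' possibly drifting centre, with optional per-frame Gaussian jitter of the
#' pair orientation.
#'
#' @param omega_deg_hr Ground-truth angular velocity (deg/hr, positive
#'   clockwise).
#' @param radius_um Half-separation of the two landmarks (µm).
#' @param center_um Initial centre (µm, image convention).
#' @param drift_um_hr Length-2 centre drift velocity (µm/hr).
#' @param angular_noise_sd_deg Per-frame sd of the orientation jitter (deg).
#' @param dt_hr Frame interval (hr).
#' @param t_max_hr Track duration (hr).
#' @param phase_deg Initial orientation (deg).
#' @param seed Integer seed.
#' @return A [landmark_track()]; ground truth in the `ground_truth`
#'   attribute.
#' @export
make_landmark_track <- function(omega_deg_hr = 50, radius_um = 3,
                                center_um = c(0, 0), drift_um_hr = c(0, 0),
                                angular_noise_sd_deg = 0, dt_hr = 0.25,
                                t_max_hr = 10, phase_deg = 0, seed = 1L) {
  t <- seq(0, t_max_hr, by = dt_hr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  jit <- if (angular_noise_sd_deg > 0) stats::rnorm(length(t), 0, angular_noise_sd_deg) else numeric(length(t))
  phi <- (phase_deg + omega_deg_hr * t + jit) * pi / 180  # y-down: + is clockwise
  cx <- center_um[1] + drift_um_hr[1] * t
  cy <- center_um[2] + drift_um_hr[2] * t
  out <- landmark_track(tibble::tibble(
    time_hr = t,
    ax_um = cx + radius_um * cos(phi),
    ay_um = cy + radius_um * sin(phi),
    bx_um = cx - radius_um * cos(phi),
    by_um = cy - radius_um * sin(phi)
  ))
  attr(out, "ground_truth") <- list(omega_deg_hr = omega_deg_hr,
                                    angular_noise_sd_deg = angular_noise_sd_deg,
                                    drift_um_hr = drift_um_hr, seed = seed)
  out
}

#' Sample a flow solution onto a PIV-style Cartesian grid
#'
#' Reconstructs image-convention `(v_x, v_y)` on a planar grid from the
#' axisymmetric solution at a chosen layer, using the clockwise-positive
#' display convention (the simulation's negative azimuthal velocity, i.e.
#' clockwise viewed from above, maps to positive displayed `v_phi`).
#'
#' @param sol A [solve_flow()] solution.
#' @param z_mode `"dorsal"`, `"ventral"` (layer at `offset_frac` of the
#'   local height from that side) or `"max_speed"` (the z of maximal planar
#'   speed per radius).
#' @param spacing_um Grid spacing (µm).
#' @param offset_frac Layer offset as a fraction of local height.
#' @param velocity_scale_um_s Multiplier converting non-dimensional
#'   velocities to µm/s (e.g. from [calibrate()]); default 1 leaves them
#'   non-dimensional.
#' @return A [planar_velocity_field()] (single frame at `time_s = 0`).
#' @export
sample_solution_to_grid <- function(sol, z_mode = c("dorsal", "ventral", "max_speed"),
                                    spacing_um = 1, offset_frac = 0.1,
                                    velocity_scale_um_s = 1) {
  z_mode <- match.arg(z_mode)
  stopifnot(inherits(sol, "flow_solution"))
  if (offset_frac <= 0 || offset_frac >= 1) {
    stop("offset_frac must be in (0, 1): layer outside the domain")
  }
  r0 <- sol$shape$r0_um
  g <- seq(-r0, r0, by = spacing_um)
  grid <- expand.grid(x_um = g, y_um = g)
  r <- sqrt(grid$x_um^2 + grid$y_um^2)
  inside <- r <= r0 * 0.99 & r > 0
  rr <- r[inside]
  h <- dorsal_height(rr, sol$shape)
  z <- switch(z_mode,
              dorsal = h * (1 - offset_frac),
              ventral = h * offset_frac,
              max_speed = {
                vapply(seq_along(rr), function(i) {
                  zs <- seq(h[i] * 0.02, h[i] * 0.98, length.out = 25)
                  fv <- flow_velocity(sol, rep(rr[i], length(zs)), zs)
                  sp <- sqrt(fv$v_rho^2 + fv$v_phi^2)
                  zs[which.max(sp)]
                }, numeric(1))
              })
  fv <- flow_velocity(sol, rr, z)
  v_r <- fv$v_rho * velocity_scale_um_s
  v_cw <- -fv$v_phi * velocity_scale_um_s  # clockwise from above -> + on screen
  x <- grid$x_um[inside]; y <- grid$y_um[inside]
  vx <- v_r * x / rr + v_cw * (-y) / rr
  vy <- v_r * y / rr + v_cw * x / rr
  df <- tibble::tibble(time_s = 0,
                       x_um = grid$x_um, y_um = grid$y_um,
                       vx_um_s = 0, vy_um_s = 0, valid = inside)
  df$vx_um_s[inside] <- vx
  df$vy_um_s[inside] <- vy
  df$vx_um_s[inside][!is.finite(vx)] <- 0
  df$vy_um_s[inside][!is.finite(vy)] <- 0
  df$valid[inside][!is.finite(vx) | !is.finite(vy)] <- FALSE
  planar_velocity_field(df, center_um = c(0, 0))
}

#' Manufactured-solution forcing for solver verification
#'
#' Given closed-form target fields as R expressions in `rho` and `z`,
#' computes (by symbolic differentiation) the strong right-hand sides that
#' make the targets exact solutions of the azimuthal and meridional
#' equations, for use with the `rhs`/`g_rho`/`g_z` overrides of
#' [solve_azimuthal()] and [solve_meridional()].
#'
#' @param vphi,vrho,vz,p Expressions (e.g. `quote(rho^2 * sin(z))`) for the
#'   target fields; any subset may be supplied.
#' @param check_incompressibility If both `vrho` and `vz` are given, verify
#'   `v_rho/rho + d(v_rho)/d(rho) + d(v_z)/dz = 0` symbolically-numerically
#'   on a sample grid and error if violated.
#' @param check_domain Numeric `c(rho_min, rho_max, z_min, z_max)` sample
#'   box for the incompressibility check.
#' @return A list of vectorised functions among `g_phi(rho, z)`,
#'   `g_rho(rho, z)`, `g_z(rho, z)`, plus evaluators `vphi`, `vrho`, `vz`,
#'   `p` for the targets.
#' @examples
#' mf <- manufactured_forcing(vphi = quote(rho * (1 - rho) * z))
#' mf$g_phi(0.5, 0.2)
#' @export
manufactured_forcing <- function(vphi = NULL, vrho = NULL, vz = NULL,
                                 p = NULL, check_incompressibility = TRUE,
                                 check_domain = c(0.3, 1, 0, 0.3)) {
  as_fun <- function(e) {
    if (is.null(e)) return(NULL)
    function(rho, z) {
      v <- eval(e, list(rho = rho, z = z))
      rep_len(v, max(length(rho), length(z)))
    }
  }
  dx <- function(e, var) stats::D(e, var)
  # operator L_c u = u_rr + u_zz + u_r / rho - c * u / rho^2
  lap_expr <- function(e, c_coef) {
    err <- dx(e, "rho"); ezz <- dx(dx(e, "z"), "z"); err2 <- dx(err, "rho")
    function(rho, z) {
      v <- eval(err2, list(rho = rho, z = z)) +
        eval(ezz, list(rho = rho, z = z)) +
        eval(err, list(rho = rho, z = z)) / rho -
        c_coef * eval(e, list(rho = rho, z = z)) / rho^2
      rep_len(v, max(length(rho), length(z)))
    }
  }
  out <- list(vphi = as_fun(vphi), vrho = as_fun(vrho), vz = as_fun(vz),
              p = as_fun(p))
  if (!is.null(vphi)) out$g_phi <- lap_expr(vphi, 1)
  d_fun <- function(expr_d) {
    force(expr_d)
    if (is.null(expr_d)) return(function(rho, z) 0)
    function(rho, z) rep_len(eval(expr_d, list(rho = rho, z = z)),
                             max(length(rho), length(z)))
  }
  if (!is.null(vrho)) {
    lr <- lap_expr(vrho, 1)
    pr <- d_fun(if (is.null(p)) NULL else dx(p, "rho"))
    out$g_rho <- function(rho, z) lr(rho, z) - pr(rho, z)
  }
  if (!is.null(vz)) {
    lz <- lap_expr(vz, 0)
    pz <- d_fun(if (is.null(p)) NULL else dx(p, "z"))
    out$g_z <- function(rho, z) lz(rho, z) - pz(rho, z)
  }
  if (check_incompressibility && !is.null(vrho) && !is.null(vz)) {
    er <- dx(vrho, "rho"); ez <- dx(vz, "z")
    rs <- seq(check_domain[1], check_domain[2], length.out = 17)
    zs <- seq(check_domain[3], check_domain[4], length.out = 17)
    gr <- expand.grid(rho = rs, z = zs)
    div <- out$vrho(gr$rho, gr$z) / gr$rho +
      rep_len(eval(er, gr), nrow(gr)) + rep_len(eval(ez, gr), nrow(gr))
    if (max(abs(div)) > 1e-8) {
      stop(sprintf("manufactured (vrho, vz) violate incompressibility (max |div| = %.3g)",
                   max(abs(div))))
    }
  }
  out
}
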
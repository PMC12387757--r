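#' Cell shape parameters for the axisymmetric dome geometry
#'
#' The meridional (rho, z) section of the cell is bounded below by the
#' substrate (z = 0), on the left by the symmetry axis (rho = 0), and above by
#' a piecewise dorsal curve made of an apical spherical cap, a tangent
#' "shoulder" circle, and a tangent straight contact line meeting the
#' substrate at angle `alpha_rad`. All lengths are in micrometres.
#'
#' @param z0_um Cell height at the axis (µm).
#' @param r0_um Cell radius, where the dorsal curve meets the substrate (µm).
#' @param r1_um Radius of the apical cap circle (µm).
#' @param rho2_um Radial position of the shoulder-circle centre (µm).
#' @param alpha_rad Contact angle of the cell edge with the substrate (rad),
#'   in (0, pi/2).
#'
#' @return An object of class `cell_shape`: a list with the five parameters
#'   plus the derived junction geometry from [derive_shape()].
#' @examples
#' shape <- cell_shape()
#' shape$derived
#' @export
cell_shape <- function(z0_um = 8.2, r0_um = 35.0, r1_um = 15.0,
                       rho2_um = 22.0, alpha_rad = 7.0 * 2 * pi / 360) {
  stopifnot(
    "z0_um must be a single positive number" = is_pos_scalar(z0_um),
    "r0_um must be a single positive number" = is_pos_scalar(r0_um),
    "r1_um must be a single positive number" = is_pos_scalar(r1_um),
    "rho2_um must be a single positive number" = is_pos_scalar(rho2_um),
    "alpha_rad must be in (0, pi/2)" =
      is_pos_scalar(alpha_rad) && alpha_rad < pi / 2,
    "rho2_um must be smaller than r0_um" = rho2_um < r0_um
  )
  params <- list(z0_um = z0_um, r0_um = r0_um, r1_um = r1_um,
                 rho2_um = rho2_um, alpha_rad = alpha_rad)
  params$derived <- derive_shape(params)
  structure(params, class = "cell_shape")
}

is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0

#' @method print cell_shape
#' @export
print.cell_shape <- function(x, ...) {
  cat("<cell_shape>\n")
  cat(sprintf("  Z0 = %.4g um, R0 = %.4g um, r1 = %.4g um, rho2 = %.4g um, alpha = %.4g rad\n",
              x$z0_um, x$r0_um, x$r1_um, x$rho2_um, x$alpha_rad))
  d <- x$derived
  cat(sprintf("  derived: rho1 = %.6g, rho3 = %.6g, r2 = %.6g, Z2 = %.6g um\n",
              d$rho1_um, d$rho3_um, d$r2_um, d$z2_um))
  invisible(x)
}

#' Derived junction geometry of the piecewise dorsal boundary
#'
#' Solves the tangency construction in closed form: the shoulder circle
#' (centre at radius `rho2_um`, height `Z2`, radius `r2`) is tangent to the
#' apical cap circle and to the straight edge line
#' `z = -tan(alpha) (rho - R0)`. `Z2` has a self-contained closed form; `r2`
#' then follows from the line-tangency condition, and the junction radii
#' `rho1` (cap/shoulder) and `rho3` (shoulder/edge line) follow from the two
#' tangency points.
#'
#' @param params A `cell_shape` object, or a bare list with fields `z0_um`,
#'   `r0_um`, `r1_um`, `rho2_um`, `alpha_rad`.
#'
#' @return A list with `rho1_um`, `rho3_um`, `r2_um`, `z2_um`.
#' @examples
#' derive_shape(cell_shape())
#' @export
derive_shape <- function(params) {
  z0 <- params$z0_um; r0 <- params$r0_um; r1 <- params$r1_um
  rho2 <- params$rho2_um; alpha <- params$alpha_rad
  derive_tangent_circle(z0, r0, r1, rho2, alpha, what = "geometry")
}

# Shared closed form: also used with (beta, Z0') for the activity band shape.
derive_tangent_circle <- function(z0, r0, r1, rho2, alpha, what = "geometry") {
  s <- sin(alpha); cc <- cos(alpha)
  if (abs(s) < 1e-8) {
    stop(sprintf("invalid %s: |sin(angle)| < 1e-8; the Z2 closed form divides by sin^2", what))
  }
  radicand <- (-r1 + (r1 - z0) * cc + r0 * s) *
    (-r1 + (r1 - z0) * cc + (r0 - 2 * rho2) * s)
  if (radicand < 0) {
    stop(sprintf(
      "invalid %s: negative square-root argument in the Z2 closed form (radicand = %.6g)",
      what, radicand))
  }
  z2 <- -(r1 - z0 - cc * (r1 + (rho2 - r0) * s) + sqrt(radicand)) / s^2
  r2 <- s * (rho2 - r0) + cc * z2
  if (!is.finite(r2) || r2 <= 0) {
    stop(sprintf("invalid %s: non-positive shoulder radius r2 = %.6g", what, r2))
  }
  rho1 <- r1 * rho2 / (r1 + r2)
  rho3 <- rho2 - r2 * s
  if (!(0 < rho1 && rho1 < rho3 && rho3 < r0)) {
    stop(sprintf(
      "invalid %s: junction radii not ordered 0 < rho1 (%.4g) < rho3 (%.4g) < R0 (%.4g)",
      what, rho1, rho3, r0))
  }
  list(rho1_um = rho1, rho3_um = rho3, r2_um = r2, z2_um = z2)
}

#' Height of the dorsal boundary
#'
#' Evaluates the piecewise dorsal curve: apical cap for `rho <= rho1`,
#' shoulder circle for `rho1 <= rho <= rho3`, straight contact line beyond.
#'
#' @param rho_um Radial positions (µm), each in `[0, r0_um]`.
#' @param shape A `cell_shape` object.
#' @return Heights z (µm), vectorised over `rho_um`.
#' @examples
#' dorsal_height(c(0, 10, 35), cell_shape())
#' @export
dorsal_height <- function(rho_um, shape) {
  stopifnot(inherits(shape, "cell_shape"))
  if (any(rho_um < -1e-9 | rho_um > shape$r0_um + 1e-9)) {
    stop("rho_um outside [0, R0]")
  }
  rho <- pmin(pmax(rho_um, 0), shape$r0_um)
  d <- shape$derived
  ifelse(rho <= d$rho1_um,
         shape$z0_um - shape$r1_um + sqrt(pmax(shape$r1_um^2 - rho^2, 0)),
         ifelse(rho <= d$rho3_um,
                d$z2_um - sqrt(pmax(d$r2_um^2 - (rho - shape$rho2_um)^2, 0)),
                -tan(shape$alpha_rad) * (rho - shape$r0_um)))
}

#' Slope dz/drho of the dorsal boundary
#'
#' Analytic derivative of [dorsal_height()], used to construct outward
#' normals for the free-slip boundary condition.
#'
#' @inheritParams dorsal_height
#' @return Slopes dz/drho, vectorised.
#' @export
dorsal_slope <- function(rho_um, shape) {
  stopifnot(inherits(shape, "cell_shape"))
  rho <- pmin(pmax(rho_um, 0), shape$r0_um)
  d <- shape$derived
  ifelse(rho <= d$rho1_um,
         -rho / sqrt(pmax(shape$r1_um^2 - rho^2, 1e-300)),
         ifelse(rho <= d$rho3_um,
                (rho - shape$rho2_um) /
                  sqrt(pmax(d$r2_um^2 - (rho - shape$rho2_um)^2, 1e-300)),
                -tan(shape$alpha_rad)))
}

#' Analytic area of the meridional cross-section
#'
#' Integral of [dorsal_height()] over `[0, R0]` by adaptive quadrature;
#' reference value for mesh-convergence checks.
#'
#' @param shape A `cell_shape` object.
#' @return Area in µm^2.
#' @export
cross_section_area <- function(shape) {
  stopifnot(inherits(shape, "cell_shape"))
  stats::integrate(function(r) dorsal_height(r, shape), 0, shape$r0_um,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}
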
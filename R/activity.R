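#' Parameters of the dorsal actomyosin activity band
#'
#' The orientational field of the concentric actomyosin band is
#' `p = S(rho, z) e_phi` with a scalar effective order parameter
#' `S in [0, 1]`. The band hugs the dorsal membrane along an auxiliary
#' "inflated" copy of the cell boundary of height `z0p_um` and edge tilt
#' `beta_rad`, with smoothed tanh edges of sharpness `lambda1_per_um`
#' (inner flank) and `lambda2_per_um` (radial cutoff at `xi3_um`), and an
#' outward offset `xi_um`.
#'
#' Defaults follow the calibrated model for the default [cell_shape()]:
#' `lambda1 = 150/R0`, `lambda2 = 20/R0` (per µm), `beta = 1.7 alpha`,
#' `xi = 0.06 R0`, `xi3 = 0.7 R0` (µm), `Z0' = 1.5 Z0`.
#'
#' @param shape A [cell_shape()] object the defaults are scaled from.
#' @param lambda1_per_um Inner-edge sharpness (1/µm).
#' @param lambda2_per_um Radial-cutoff sharpness (1/µm).
#' @param beta_rad Band tilt angle (rad), in (0, pi/2).
#' @param xi_um Outward offset of the band from the inflated boundary (µm).
#' @param xi3_um Radial cutoff position (µm).
#' @param z0p_um Height of the inflated auxiliary boundary (µm).
#' @param lambda_eq19_per_um Sharpness of the circle-distance branch of the
#'   band (1/µm); defaults to `lambda1_per_um`, which plays the same
#'   inner-edge role.
#' @return An object of class `activity_params` including the derived
#'   inflated-shoulder geometry from [derive_activity_shape()].
#' @examples
#' act <- activity_params(cell_shape())
#' act$derived
#' @export
activity_params <- function(shape = cell_shape(),
                            lambda1_per_um = 150 / shape$r0_um,
                            lambda2_per_um = 20 / shape$r0_um,
                            beta_rad = 1.7 * shape$alpha_rad,
                            xi_um = 0.06 * shape$r0_um,
                            xi3_um = 0.7 * shape$r0_um,
                            z0p_um = 1.5 * shape$z0_um,
                            lambda_eq19_per_um = lambda1_per_um) {
  stopifnot(
    inherits(shape, "cell_shape"),
    "lambda1_per_um must be > 0" = is_pos_scalar(lambda1_per_um),
    "lambda2_per_um must be > 0" = is_pos_scalar(lambda2_per_um),
    "beta_rad must be in (0, pi/2)" = is_pos_scalar(beta_rad) && beta_rad < pi / 2,
    "xi_um must be >= 0" = is.numeric(xi_um) && length(xi_um) == 1 && xi_um >= 0,
    "xi3_um must be >= 0" = is.numeric(xi3_um) && length(xi3_um) == 1 && xi3_um >= 0,
    "z0p_um must be > 0" = is_pos_scalar(z0p_um),
    "lambda_eq19_per_um must be > 0" = is_pos_scalar(lambda_eq19_per_um)
  )
  act <- list(lambda1_per_um = lambda1_per_um, lambda2_per_um = lambda2_per_um,
              beta_rad = beta_rad, xi_um = xi_um, xi3_um = xi3_um,
              z0p_um = z0p_um, lambda_eq19_per_um = lambda_eq19_per_um)
  act$derived <- derive_activity_shape(shape, act)
  structure(c(act, list(shape = shape)), class = "activity_params")
}

#' @method print activity_params
#' @export
print.activity_params <- function(x, ...) {
  cat("<activity_params>\n")
  cat(sprintf("  lambda1 = %.4g /um, lambda2 = %.4g /um, beta = %.4g rad\n",
              x$lambda1_per_um, x$lambda2_per_um, x$beta_rad))
  cat(sprintf("  xi = %.4g um, xi3 = %.4g um, Z0' = %.4g um\n",
              x$xi_um, x$xi3_um, x$z0p_um))
  d <- x$derived
  cat(sprintf("  derived: rho3' = %.6g, r2' = %.6g, Z2' = %.6g um\n",
              d$rho3p_um, d$r2p_um, d$z2p_um))
  invisible(x)
}

#' Derived shoulder geometry of the inflated activity boundary
#'
#' Applies the same tangent-circle closed form as [derive_shape()], with the
#' band tilt `beta` in place of the contact angle and the inflated height
#' `Z0'` in place of the cell height.
#'
#' @param shape A [cell_shape()] object.
#' @param act An `activity_params` object or bare list with `beta_rad`,
#'   `z0p_um`.
#' @return A list with `rho3p_um`, `r2p_um`, `z2p_um`.
#' @export
derive_activity_shape <- function(shape, act) {
  d <- derive_tangent_circle(act$z0p_um, shape$r0_um, shape$r1_um,
                             shape$rho2_um, act$beta_rad,
                             what = "activity geometry")
  list(rho3p_um = d$rho3_um, r2p_um = d$r2_um, z2p_um = d$z2_um)
}

# Signed branch selector: the ray through the junction of the inflated
# shoulder arc and its tangent edge line, perpendicular to the band
# direction. sel <= 0 is the inner (shoulder-arc) side, sel > 0 the outer
# (edge-line) side.
activity_selector <- function(rho, z, shape, act) {
  cb <- cos(act$beta_rad); sb <- sin(act$beta_rad)
  cb * rho - sb * z - act$derived$rho3p_um / cb +
    sb * tan(act$beta_rad) * shape$r0_um
}

#' Effective order parameter S of the actomyosin band
#'
#' Evaluates `S(rho, z) in [0, 1]`. On the outer side of the junction ray
#' (see Details) the band is the product of two smoothed steps: above the
#' inflated edge line (sharpness `lambda1`, offset `xi`) and radially inside
#' the cutoff `xi3` (sharpness `lambda2`). On the inner side the band is a
#' smoothed step on the distance to the inflated shoulder-circle centre
#' (radius `r2' + xi`, sharpness `lambda_eq19`), which lets the band die
#' away toward the apex and gives the ring its inner edge.
#'
#' @details The two branches are tangent continuations of one another; which
#' applies is decided by the sign of a ray through the shoulder/edge-line
#' junction of the inflated boundary. Continuity across the ray is a checked
#' property, not an assumption (see the package tests).
#'
#' @param rho_um,z_um Coordinates (µm), vectorised (recycled to a common
#'   length).
#' @param shape A [cell_shape()] object.
#' @param act An [activity_params()] object.
#' @return Values of S, same length as the inputs.
#' @examples
#' act <- activity_params()
#' order_parameter(c(5, 15, 30), c(0.5, 2.5, 0.3), cell_shape(), act)
#' @export
order_parameter <- function(rho_um, z_um, shape, act) {
  n <- max(length(rho_um), length(z_um))
  rho <- rep_len(rho_um, n); z <- rep_len(z_um, n)
  cb <- cos(act$beta_rad); sb <- sin(act$beta_rad)
  d <- act$derived
  sel <- activity_selector(rho, z, shape, act)
  # outer branch: tilted edge-line band with radial cutoff
  f1 <- 0.5 * tanh(act$lambda1_per_um *
                     (sb * rho + cb * z - sb * shape$r0_um + act$xi_um)) + 0.5
  f2 <- 0.5 * tanh(-act$lambda2_per_um *
                     (cb * rho - sb * z - act$xi3_um)) + 0.5
  s_outer <- f1 * f2
  # inner branch: distance to the inflated shoulder-circle centre
  dist <- sqrt((rho - shape$rho2_um)^2 + (z - d$z2p_um)^2)
  s_inner <- 0.5 * tanh(act$lambda_eq19_per_um *
                          (d$r2p_um + act$xi_um - dist)) + 0.5
  s <- ifelse(sel <= 0, s_inner, s_outer)
  pmin(pmax(s, 0), 1)
}

#' Analytic z-derivative of the order parameter
#'
#' Exact derivative of [order_parameter()] with respect to z, needed for the
#' torque-dipole forcing `S dS/dz` of the azimuthal flow equation.
#'
#' @inheritParams order_parameter
#' @return dS/dz in 1/µm, same length as the inputs.
#' @export
order_parameter_dz <- function(rho_um, z_um, shape, act) {
  n <- max(length(rho_um), length(z_um))
  rho <- rep_len(rho_um, n); z <- rep_len(z_um, n)
  cb <- cos(act$beta_rad); sb <- sin(act$beta_rad)
  d <- act$derived
  sel <- activity_selector(rho, z, shape, act)
  a1 <- act$lambda1_per_um * (sb * rho + cb * z - sb * shape$r0_um + act$xi_um)
  a2 <- -act$lambda2_per_um * (cb * rho - sb * z - act$xi3_um)
  f1 <- 0.5 * tanh(a1) + 0.5
  f2 <- 0.5 * tanh(a2) + 0.5
  df1 <- 0.5 * (1 - tanh(a1)^2) * act$lambda1_per_um * cb
  df2 <- 0.5 * (1 - tanh(a2)^2) * act$lambda2_per_um * sb
  d_outer <- df1 * f2 + f1 * df2
  dist <- pmax(sqrt((rho - shape$rho2_um)^2 + (z - d$z2p_um)^2), 1e-300)
  a3 <- act$lambda_eq19_per_um * (d$r2p_um + act$xi_um - dist)
  d_inner <- 0.5 * (1 - tanh(a3)^2) * act$lambda_eq19_per_um *
    (d$z2p_um - z) / dist
  ifelse(sel <= 0, d_inner, d_outer)
}

#' Bundle the activity field into evaluator closures
#'
#' Convenience wrapper used by the flow solver: returns vectorised functions
#' of `(rho_um, z_um)` for S and dS/dz.
#'
#' @inheritParams order_parameter
#' @return A list with elements `S`, `dSdz` (functions), `shape`, `act`.
#' @export
activity_field <- function(shape, act) {
  force(shape); force(act)
  list(S = function(rho_um, z_um) order_parameter(rho_um, z_um, shape, act),
       dSdz = function(rho_um, z_um) order_parameter_dz(rho_um, z_um, shape, act),
       shape = shape, act = act)
}
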
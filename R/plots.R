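# ggplot2 autoplot methods for the result types.

#' Plot a flow solution
#'
#' Raster maps of the order parameter and the non-dimensional velocity
#' components over the meridional section.
#'
#' @param object A `flow_solution`.
#' @param n Grid resolution per direction.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flow_solution
#' @export
autoplot.flow_solution <- function(object, n = 120, ...) {
  shape <- object$shape
  rho <- seq(shape$r0_um / (2 * n), shape$r0_um * (1 - 1 / (2 * n)), length.out = n)
  df <- purrr::map_dfr(rho, function(r) {
    h <- dorsal_height(r, shape)
    z <- seq(h / 60, h * (1 - 1 / 60), length.out = 30)
    flow_velocity(object, rep(r, length(z)), z)
  })
  long <- tidyr::pivot_longer(df, cols = c("S", "v_phi", "v_rho", "v_z"),
                              names_to = "field", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$rho_um, .data$z_um,
                                     colour = .data$value)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(~field, scales = "free") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "rho (um)", y = "z (um)",
                  title = "Meridional fields (non-dimensional velocities)")
}

#' Plot a z-averaged angular-velocity profile
#'
#' @param object An `angular_velocity_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angular_velocity_profile
#' @export
autoplot.angular_velocity_profile <- function(object, ...) {
  has_scaled <- "rho_scaled" %in% names(object)
  has_deg <- "omega_deg_hr" %in% names(object)
  x <- if (has_scaled) "rho_scaled" else "rho_um"
  y <- if (has_deg) "omega_deg_hr" else "omega_cw"
  p <- ggplot2::ggplot(object, ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (has_scaled) "rho / rho_a" else "rho (um)",
      y = if (has_deg) "angular velocity (deg/hr, clockwise +)"
          else "angular velocity (non-dim., clockwise +)")
  if (has_scaled) {
    p <- p + ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot a binned radial profile from PIV post-processing
#'
#' @param object A `radial_profile`.
#' @param quantity One of `"omega"`, `"v_phi"`, `"v_r"`.
#' @param ... Unused.
#' @return A ggplot object with mean line and SEM ribbon.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, quantity = c("omega", "v_phi", "v_r"),
                                    ...) {
  quantity <- match.arg(quantity)
  m <- paste0(quantity, "_mean"); s <- paste0(quantity, "_sem")
  x <- if ("r_scaled" %in% names(object)) "r_scaled" else "r_mid_um"
  d <- object[object$n > 0, ]
  ylab <- c(omega = "angular velocity (deg/hr)",
            v_phi = "azimuthal velocity (um/s)",
            v_r = "radial velocity (um/s)")[[quantity]]
  ggplot2::ggplot(d, ggplot2::aes(.data[[x]], .data[[m]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[m]] - .data[[s]],
                                      ymax = .data[[m]] + .data[[s]]),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (x == "r_scaled") "r / ring inner radius" else "r (um)",
                  y = ylab)
}

#' Plot a cumulative rotation trace
#'
#' @param object A `rotation_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rotation_trace
#' @export
autoplot.rotation_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_hr, .data$theta_deg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (hr)",
                  y = "cumulative angle (deg, clockwise +)")
}
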
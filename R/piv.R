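# Post-processing of gridded planar velocity fields (as exported by PIV
# software) into azimuthal/radial components about the cell centre, and
# temporally / angularly averaged radial profiles.
#
# Image conventions throughout: x to the right, y increasing downward, so a
# positive azimuthal velocity v_phi = x_hat v_y - y_hat v_x corresponds to
# clockwise motion as displayed, and positive angular velocity means
# clockwise rotation.

#' Assemble a planar velocity-field series
#'
#' @param df A data frame with columns `time_s`, `x_um`, `y_um`, `vx_um_s`,
#'   `vy_um_s` and optionally `valid` (logical, default all TRUE). The
#'   `(x, y)` positions must lie on a common rectilinear grid across frames;
#'   y follows the image convention (increasing downward).
#' @param center_um Numeric length-2: the cell centre `(x, y)` in µm (in the
#'   experiment, the xy position of the cell's highest point). Used as the
#'   origin of the polar decomposition.
#' @return A tibble of class `planar_velocity_field` with attributes
#'   `center_um` and `spacing_um`.
#' @export
planar_velocity_field <- function(df, center_um) {
  need <- c("time_s", "x_um", "y_um", "vx_um_s", "vy_um_s")
  stopifnot(all(need %in% names(df)),
            is.numeric(center_um), length(center_um) == 2)
  out <- tibble::as_tibble(df)
  if (!"valid" %in% names(out)) out$valid <- TRUE
  xs <- sort(unique(out$x_um)); ys <- sort(unique(out$y_um))
  dx <- if (length(xs) > 1) min(diff(xs)) else NA_real_
  dy <- if (length(ys) > 1) min(diff(ys)) else NA_real_
  spacing <- min(dx, dy, na.rm = TRUE)
  if (is.finite(spacing)) {
    ok_x <- all(abs((out$x_um - xs[1]) / spacing -
                      round((out$x_um - xs[1]) / spacing)) < 1e-6)
    ok_y <- all(abs((out$y_um - ys[1]) / spacing -
                      round((out$y_um - ys[1]) / spacing)) < 1e-6)
    if (!ok_x || !ok_y) stop("x_um/y_um do not lie on a uniform grid")
  }
  rng_x <- range(out$x_um[out$valid]); rng_y <- range(out$y_um[out$valid])
  if (center_um[1] < rng_x[1] || center_um[1] > rng_x[2] ||
      center_um[2] < rng_y[1] || center_um[2] > rng_y[2]) {
    stop("center_um lies outside the valid grid region")
  }
  structure(out, center_um = center_um, spacing_um = spacing,
            class = c("planar_velocity_field", class(out)))
}

#' Estimate the cell centre as the centroid of the valid mask
#'
#' Helper for when no height-map centre is available; the primary path is a
#' user-supplied centre.
#'
#' @param field A `planar_velocity_field` or compatible data frame.
#' @return Numeric length-2 centre (µm).
#' @export
mask_centroid <- function(field) {
  v <- field[field$valid, ]
  c(mean(v$x_um), mean(v$y_um))
}

#' Decompose a planar velocity field into azimuthal and radial components
#'
#' Applies `v_phi = x_hat v_y - y_hat v_x`, `v_r = x_hat v_x + y_hat v_y`
#' with `(x, y)` relative to the cell centre and `r = sqrt(x^2 + y^2)`, and
#' the angular velocity `omega = v_phi / r`. In image coordinates (y down)
#' positive `v_phi` and `omega` are clockwise as displayed.
#'
#' @param field A [planar_velocity_field()].
#' @param center_um Override of the stored centre.
#' @param r_min_um Radii below this are excluded from `omega` (NA) to avoid
#'   dividing by a vanishing radius; default one grid spacing.
#' @return The input tibble with added columns `r_um`, `v_phi_um_s`,
#'   `v_r_um_s`, `omega_rad_s` (class `polar_decomposition`).
#' @export
decompose_velocity <- function(field, center_um = attr(field, "center_um"),
                               r_min_um = attr(field, "spacing_um")) {
  stopifnot(!is.null(center_um))
  if (is.null(r_min_um) || !is.finite(r_min_um)) r_min_um <- 0
  x <- field$x_um - center_um[1]
  y <- field$y_um - center_um[2]
  r <- sqrt(x^2 + y^2)
  xh <- ifelse(r > 0, x / r, 0)
  yh <- ifelse(r > 0, y / r, 0)
  out <- field
  out$r_um <- r
  out$v_phi_um_s <- xh * field$vy_um_s - yh * field$vx_um_s
  out$v_r_um_s <- xh * field$vx_um_s + yh * field$vy_um_s
  out$omega_rad_s <- ifelse(r >= max(r_min_um, 1e-12),
                            out$v_phi_um_s / r, NA_real_)
  if (!inherits(out, "polar_decomposition")) {
    class(out) <- c("polar_decomposition", class(out))
  }
  attr(out, "center_um") <- center_um
  attr(out, "r_min_um") <- r_min_um
  out
}

#' Temporal average of a decomposed velocity series
#'
#' Per-grid-point mean over the frames in which the point is valid, taken
#' before any angular averaging (profiles are formed from temporal averages
#' at each spatial point).
#'
#' @param decomp A `polar_decomposition` tibble (multiple frames).
#' @return A single-"frame" `polar_decomposition` tibble (`time_s` dropped,
#'   `n_frames` added).
#' @export
temporal_average <- function(decomp) {
  stopifnot(inherits(decomp, "polar_decomposition"))
  if (length(unique(decomp$time_s)) < 2) {
    stop("temporal_average needs at least 2 frames")
  }
  valid <- decomp[decomp$valid, ]
  if (!nrow(valid)) stop("no grid point is valid in any frame")
  out <- valid |>
    dplyr::group_by(.data$x_um, .data$y_um) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      r_um = .data$r_um[1],
      vx_um_s = mean(.data$vx_um_s),
      vy_um_s = mean(.data$vy_um_s),
      v_phi_um_s = mean(.data$v_phi_um_s),
      v_r_um_s = mean(.data$v_r_um_s),
      omega_rad_s = mean(.data$omega_rad_s),
      .groups = "drop")
  out$valid <- TRUE
  class(out) <- c("polar_decomposition", class(tibble::tibble()))
  attr(out, "center_um") <- attr(decomp, "center_um")
  attr(out, "r_min_um") <- attr(decomp, "r_min_um")
  attr(out, "spacing_um") <- attr(decomp, "spacing_um")
  out
}

#' Angular (annular-bin) average into a radial profile
#'
#' Bins the temporally averaged field by radius and reports per-bin mean and
#' standard error of the mean for the azimuthal velocity, radial velocity
#' and angular velocity.
#'
#' @param decomp A temporally averaged `polar_decomposition` (one value per
#'   grid point).
#' @param bin_width_um Bin width; default one grid spacing.
#' @param r_max_um Outer edge of the last bin; default the largest valid
#'   radius.
#' @return A tibble of class `radial_profile`: `r_mid_um`, `n`, and
#'   `{v_phi,v_r,omega}_{mean,sem}` columns. Empty bins keep `n = 0` and NA
#'   values. `omega` columns are in degrees/hr.
#' @export
angular_average <- function(decomp, bin_width_um = attr(decomp, "spacing_um"),
                            r_max_um = NULL) {
  stopifnot(inherits(decomp, "polar_decomposition"))
  if ("time_s" %in% names(decomp) && length(unique(decomp$time_s)) > 1) {
    stop("angular_average expects a temporally averaged field; run temporal_average() first")
  }
  if (is.null(bin_width_um) || !is.finite(bin_width_um)) bin_width_um <- 1
  d <- decomp[decomp$valid & decomp$r_um > 0, ]
  if (is.null(r_max_um)) r_max_um <- max(d$r_um)
  breaks <- seq(0, r_max_um + bin_width_um, by = bin_width_um)
  d$bin <- findInterval(d$r_um, breaks, rightmost.closed = TRUE)
  d <- d[d$bin >= 1 & d$bin < length(breaks), ]
  rad2deghr <- (180 / pi) * 3600
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  mean_f <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else mean(x)
  }
  agg <- d |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      v_phi_mean = mean_f(.data$v_phi_um_s),
      v_phi_sem = sem(.data$v_phi_um_s),
      v_r_mean = mean_f(.data$v_r_um_s),
      v_r_sem = sem(.data$v_r_um_s),
      omega_mean = mean_f(.data$omega_rad_s) * rad2deghr,
      omega_sem = sem(.data$omega_rad_s) * rad2deghr,
      .groups = "drop")
  all_bins <- tibble::tibble(bin = seq_len(length(breaks) - 1))
  out <- dplyr::left_join(all_bins, agg, by = "bin")
  out$n[is.na(out$n)] <- 0L
  out$r_mid_um <- (breaks[out$bin] + breaks[out$bin + 1]) / 2
  out <- dplyr::select(out, "r_mid_um", "n", dplyr::everything(), -"bin")
  class(out) <- c("radial_profile", class(out))
  attr(out, "bin_width_um") <- bin_width_um
  out
}

#' Rescale a radial profile by the actomyosin-ring inner radius
#'
#' Divides the radius axis by a manually identified ring inner radius
#' (values are unchanged), enabling averaging across cells of different
#' size.
#'
#' @param profile A `radial_profile`.
#' @param ring_inner_radius_um Positive ring inner radius (µm).
#' @return The profile with an added/updated `r_scaled` column.
#' @export
rescale_radius <- function(profile, ring_inner_radius_um) {
  stopifnot(inherits(profile, "radial_profile"))
  if (!is_pos_scalar(ring_inner_radius_um)) {
    stop("ring_inner_radius_um must be a positive number")
  }
  profile$r_scaled <- profile$r_mid_um / ring_inner_radius_um
  attr(profile, "ring_inner_radius_um") <- ring_inner_radius_um
  profile
}

#' Read PIV text exports into a planar velocity-field series
#'
#' Reads one delimited text file per frame with columns (in order or named)
#' x, y, u, v and optionally a validity flag, the common PIV text export.
#'
#' @param paths Character vector of per-frame file paths, in time order.
#' @param frame_times_s Numeric vector of frame times (s), one per file.
#' @param center_um Cell centre passed to [planar_velocity_field()].
#' @param sep Field separator (default `","`).
#' @return A [planar_velocity_field()] tibble.
#' @export
read_piv_series <- function(paths, frame_times_s, center_um, sep = ",") {
  stopifnot(length(paths) == length(frame_times_s))
  frames <- purrr::map2(paths, frame_times_s, function(p, t) {
    d <- utils::read.table(p, header = TRUE, sep = sep)
    nm <- tolower(names(d))
    pick <- function(cands, k) {
      j <- which(nm %in% cands)[1]
      if (is.na(j)) k else j
    }
    tibble::tibble(
      time_s = t,
      x_um = d[[pick(c("x", "x_um"), 1)]],
      y_um = d[[pick(c("y", "y_um"), 2)]],
      vx_um_s = d[[pick(c("u", "vx", "vx_um_s"), 3)]],
      vy_um_s = d[[pick(c("v", "vy", "vy_um_s"), 4)]],
      valid = if (ncol(d) >= 5) as.logical(d[[pick(c("mask", "valid", "flag"), 5)]]) else TRUE
    )
  })
  planar_velocity_field(dplyr::bind_rows(frames), center_um = center_um)
}

#' Write a radial profile as tidy CSV
#'
#' One row per bin and quantity: columns `r_mid_um`, `r_scaled` (if
#' present), `quantity`, `mean`, `sem`, `n`.
#'
#' @param profile A `radial_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_radial_profile_csv <- function(profile, path) {
  long <- tidyr::pivot_longer(
    profile,
    cols = dplyr::all_of(c("v_phi_mean", "v_phi_sem", "v_r_mean", "v_r_sem",
                           "omega_mean", "omega_sem")),
    names_to = c("quantity", ".value"),
    names_pattern = "(v_phi|v_r|omega)_(mean|sem)")
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
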
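# Quantification of nuclear rotation from two tracked nucleoli: cumulative
# rotation angle of the connecting line and windowed average angular
# velocity, clockwise-positive in the displayed (y-down) image convention.

#' Assemble a two-landmark track
#'
#' @param df A data frame with columns `time_hr`, `ax_um`, `ay_um`, `bx_um`,
#'   `by_um` and optionally `valid`. Positions follow the image convention
#'   (y increasing downward). Times must be strictly increasing.
#' @param min_separation_um Frames where the two landmarks are closer than
#'   this are treated as invalid (default 1e-6).
#' @return A tibble of class `landmark_track`.
#' @export
landmark_track <- function(df, min_separation_um = 1e-6) {
  need <- c("time_hr", "ax_um", "ay_um", "bx_um", "by_um")
  stopifnot(all(need %in% names(df)))
  out <- tibble::as_tibble(df)
  if (!"valid" %in% names(out)) out$valid <- TRUE
  if (is.unsorted(out$time_hr, strictly = TRUE)) {
    stop("time_hr must be strictly increasing")
  }
  sep <- sqrt((out$bx_um - out$ax_um)^2 + (out$by_um - out$ay_um)^2)
  coincident <- out$valid & sep <= min_separation_um
  if (any(coincident)) {
    warning(sprintf("%d frame(s) with coincident landmarks dropped",
                    sum(coincident)))
    out$valid[coincident] <- FALSE
  }
  structure(out, class = c("landmark_track", class(out)))
}

wrap_angle <- function(d, period) {
  # wrap into (-period/2, period/2]
  w <- d - period * floor(d / period + 0.5)
  ifelse(w == -period / 2, period / 2, w)
}

#' Cumulative rotation angle of the landmark pair
#'
#' The orientation of the vector from landmark A to landmark B is taken per
#' frame via the two-argument arctangent in image coordinates; successive
#' differences are wrapped into (-180, 180] degrees (vector mode) or
#' (-90, 90] (line mode, robust to label swaps) and accumulated, starting at
#' zero. In the y-down display convention, clockwise rotation on screen
#' accumulates positive angle.
#'
#' @param track A [landmark_track()].
#' @param mode `"vector"` (identified landmarks, period 360) or `"line"`
#'   (unlabelled pair, period 180).
#' @param max_gap Maximum number of consecutive invalid frames tolerated
#'   before an error (sampling no longer constrains the winding).
#' @return A tibble of class `rotation_trace` with `time_hr` and `theta_deg`
#'   (cumulative, clockwise-positive), one row per valid frame.
#' @examples
#' tr <- make_landmark_track(omega_deg_hr = 50, t_max_hr = 10, dt_hr = 0.25)
#' tail(cumulative_angle(tr), 1) # 500 degrees after 10 hr
#' @export
cumulative_angle <- function(track, mode = c("vector", "line"), max_gap = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "landmark_track"))
  d <- track[track$valid, ]
  if (nrow(d) < 2) stop("need at least 2 valid frames")
  idx <- which(track$valid)
  if (length(idx) > 1 && max(diff(idx)) > max_gap + 1) {
    stop(sprintf("gap of more than max_gap = %d consecutive invalid frames", max_gap))
  }
  ang <- atan2(d$by_um - d$ay_um, d$bx_um - d$ax_um) * 180 / pi
  period <- if (mode == "vector") 360 else 180
  dtheta <- wrap_angle(diff(ang), period)
  out <- tibble::tibble(time_hr = d$time_hr, theta_deg = c(0, cumsum(dtheta)))
  structure(out, mode = mode, class = c("rotation_trace", class(out)))
}

#' Average angular velocity over a time window
#'
#' Slope of the cumulative angle between the window endpoints, with endpoint
#' values linearly interpolated between frames. The window start is an
#' explicit argument because the measurement origin differs between
#' experimental designs (e.g. imaging start vs a delay for inhibitors to
#' act).
#'
#' @param trace A [cumulative_angle()] trace.
#' @param window Numeric length-2 `(t_start, t_end)` in hours, inside the
#'   trace support.
#' @return Mean angular velocity in degrees/hr (positive clockwise).
#' @export
mean_angular_velocity <- function(trace, window) {
  stopifnot(inherits(trace, "rotation_trace"),
            is.numeric(window), length(window) == 2, window[2] > window[1])
  t <- trace$time_hr
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
    stop("window outside the trace support")
  }
  th <- stats::approx(t, trace$theta_deg, xout = pmin(pmax(window, t[1]), t[length(t)]))$y
  (th[2] - th[1]) / (window[2] - window[1])
}

#' @method glance rotation_trace
#' @export
glance.rotation_trace <- function(x, ...) {
  span <- range(x$time_hr)
  tibble::tibble(
    t_start_hr = span[1], t_end_hr = span[2],
    n_frames = nrow(x),
    total_angle_deg = x$theta_deg[nrow(x)] - x$theta_deg[1],
    mean_omega_deg_hr = (x$theta_deg[nrow(x)] - x$theta_deg[1]) / diff(span),
    mode = attr(x, "mode")
  )
}

#' Read a landmark track from CSV
#'
#' Expects columns `time_hr, ax_um, ay_um, bx_um, by_um[, valid]` (or the
#' short names `t, ax, ay, bx, by[, valid]`).
#'
#' @param path CSV path.
#' @return A [landmark_track()].
#' @export
read_landmark_track <- function(path) {
  d <- utils::read.csv(path)
  nm <- names(d)
  ren <- c(t = "time_hr", ax = "ax_um", ay = "ay_um", bx = "bx_um", by = "by_um")
  for (k in names(ren)) if (k %in% nm) names(d)[nm == k] <- ren[[k]]
  landmark_track(d)
}
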
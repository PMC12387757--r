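test_that("a rigid clockwise track accumulates the exact angle and rate", {
  tr <- make_landmark_track(omega_deg_hr = 50, t_max_hr = 10, dt_hr = 0.25)
  ca <- cumulative_angle(tr)
  expect_equal(ca$theta_deg[1], 0)
  expect_equal(ca$theta_deg[nrow(ca)], 500, tolerance = 1e-9)
  expect_equal(mean_angular_velocity(ca, c(0, 10)), 50, tolerance = 1e-9)
  static <- make_landmark_track(omega_deg_hr = 0, t_max_hr = 5)
  expect_equal(max(abs(cumulative_angle(static)$theta_deg)), 0)
})

test_that("unwrapping survives repeated +-180 crossings", {
  # 3.5 turns crosses the wrap boundary repeatedly; compare to the exact
  # integral of the angular increments
  tr <- make_landmark_track(omega_deg_hr = 126, t_max_hr = 10, dt_hr = 0.25,
                            phase_deg = 171)
  ca <- cumulative_angle(tr)
  expect_equal(ca$theta_deg, 126 * ca$time_hr, tolerance = 1e-9)
  expect_true(all(abs(diff(ca$theta_deg)) < 180))
})

test_that("the angle is invariant to label swap, translation, and negates under time reversal", {
  tr <- make_landmark_track(omega_deg_hr = 73, t_max_hr = 6, dt_hr = 0.2,
                            angular_noise_sd_deg = 3, seed = 9)
  ca <- cumulative_angle(tr)
  swapped <- landmark_track(dplyr::rename(tibble::as_tibble(tr),
                                          ax_um = "bx_um", bx_um = "ax_um",
                                          ay_um = "by_um", by_um = "ay_um"))
  expect_equal(cumulative_angle(swapped, mode = "line")$theta_deg,
               cumulative_angle(tr, mode = "line")$theta_deg, tolerance = 1e-9)
  drift <- make_landmark_track(omega_deg_hr = 73, t_max_hr = 6, dt_hr = 0.2,
                               angular_noise_sd_deg = 3, seed = 9,
                               drift_um_hr = c(2, -1))
  expect_equal(cumulative_angle(drift)$theta_deg, ca$theta_deg,
               tolerance = 1e-9)
  rev_df <- tibble::as_tibble(tr)[rev(seq_len(nrow(tr))), ]
  rev_df$time_hr <- max(tr$time_hr) - rev_df$time_hr
  ca_rev <- cumulative_angle(landmark_track(rev_df))
  expect_equal(ca_rev$theta_deg[nrow(ca_rev)], -ca$theta_deg[nrow(ca)],
               tolerance = 1e-9)
})

test_that("windowed average interpolates endpoints and validates the window", {
  tr <- make_landmark_track(omega_deg_hr = 40, t_max_hr = 8, dt_hr = 0.5)
  ca <- cumulative_angle(tr)
  expect_equal(mean_angular_velocity(ca, c(1.3, 6.7)), 40, tolerance = 1e-9)
  expect_equal(mean_angular_velocity(ca, c(0, 8)), 40, tolerance = 1e-9)
  expect_error(mean_angular_velocity(ca, c(-1, 5)), "window")
  expect_error(mean_angular_velocity(ca, c(5, 9)), "window")
})

test_that("orientation jitter leaves the windowed rate unbiased", {
  rates <- vapply(1:100, function(s) {
    tr <- make_landmark_track(omega_deg_hr = 50, t_max_hr = 10, dt_hr = 0.25,
                              angular_noise_sd_deg = 5, seed = s)
    mean_angular_velocity(cumulative_angle(tr), c(0, 10))
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 50), 3 * se + 1e-9)
})

test_that("degenerate tracks are caught", {
  base <- tibble::tibble(time_hr = c(0, 1, 2),
                         ax_um = c(0, 0, 0), ay_um = c(0, 0, 0),
                         bx_um = c(1, 0, 1), by_um = c(0, 0, 0))
  expect_warning(tr <- landmark_track(base), "coincident")
  expect_false(tr$valid[2])
  expect_error(landmark_track(dplyr::mutate(base, time_hr = c(0, 0, 1))),
               "increasing")
  many <- make_landmark_track(t_max_hr = 5, dt_hr = 0.25)
  many$valid[3:11] <- FALSE
  expect_error(cumulative_angle(landmark_track(tibble::as_tibble(many))),
               "max_gap")
})
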
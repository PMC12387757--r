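shape <- cell_shape()
act <- activity_params(shape)

test_that("z-averaged angular velocity is exact for rigid-body and zero flow", {
  omega_nd <- 0.3
  rigid <- function(rho_um, z_um) -omega_nd * rho_um / shape$r0_um
  prof <- z_average_omega(rigid, n_rho = 50, shape = shape)
  expect_equal(prof$omega_cw, rep(omega_nd, nrow(prof)), tolerance = 1e-12)
  zero_sol <- solve_flow(shape, act, solver_config(zeta = 0, h_um = 1.5))
  prof0 <- z_average_omega(zero_sol, n_rho = 40)
  expect_equal(max(abs(prof0$omega_cw)), 0, tolerance = 1e-14)
})

test_that("profile of the solved flow peaks once, near the ring inner radius", {
  sol <- get_test_solution()
  prof <- angular_velocity_profile(sol)
  i <- which.max(prof$omega_cw)
  expect_gt(i, 1)
  expect_lt(i, nrow(prof))
  # single interior maximum: monotone rise then fall (allowing tiny numerical
  # wiggles below 0.5% of the peak)
  tol <- 5e-3 * max(prof$omega_cw)
  expect_true(all(diff(prof$omega_cw[1:i]) > -tol))
  expect_true(all(diff(prof$omega_cw[i:nrow(prof)]) < tol))
  peak <- attr(prof, "peak")
  expect_gt(peak$peak_location_scaled, 0.8)
  expect_lt(peak$peak_location_scaled, 1.2)
})

test_that("ring inner radius is threshold-stable and errors when never reached", {
  rho_a <- ring_inner_radius(shape, act)
  expect_gt(rho_a, 0)
  expect_lt(rho_a, shape$r0_um)
  fine <- ring_inner_radius(shape, act, n_scan = 800)
  expect_lt(abs(rho_a - fine), shape$r0_um / 400 + 2e-3)
  # a saturated band reaches the threshold at the first scan point
  act_sat <- activity_params(shape, xi_um = 1000)
  expect_equal(ring_inner_radius(shape, act_sat), 0)
  expect_error(ring_inner_radius(shape, act, threshold = 2), "threshold")
})

test_that("parabolic peak interpolation is exact on a parabola and flags boundary maxima", {
  x <- seq(10, 25, by = 0.5)
  prof <- tibble::tibble(rho_um = x, omega_cw = 5 - (x - 17.3)^2)
  pk <- peak_of_profile(prof)
  expect_equal(pk$peak_rho_um, 17.3, tolerance = 1e-6)
  expect_equal(pk$peak_value, 5, tolerance = 1e-6)
  expect_false(pk$at_boundary)
  rising <- tibble::tibble(rho_um = x, omega_cw = x)
  expect_true(peak_of_profile(rising)$at_boundary)
})

test_that("calibration identities hold exactly and scale as definitions require", {
  cal <- calibrate(2e-4, 1e-2, 35)
  expect_equal(cal$velocity_scale_um_s, 50)
  expect_equal(cal$time_scale_s, 0.7)
  expect_equal(calibrate(0.123, 0.123, 35)$velocity_scale_um_s, 1)
  expect_equal(calibrate(0.123, 0.123, 35)$time_scale_s, 35)
  k <- 3.7
  expect_equal(calibrate(2e-4, k * 1e-2, 35)$velocity_scale_um_s, k * 50)
  expect_equal(calibrate(2e-4, k * 1e-2, 35)$time_scale_s, 0.7 / k)
  expect_error(calibrate(0, 1e-2, 35), "positive")
  # a rigid rotation at omega_nd converts consistently to deg/hr
  expect_equal(omega_deg_per_hr(1, cal), (180 / pi) * 3600 / 0.7)
})

test_that("surface swirl classification matches the flow structure", {
  sol <- get_test_solution()
  dors <- surface_swirl(sol, "dorsal")
  vent <- surface_swirl(sol, "ventral")
  expect_equal(dors$handedness, "sinistral")
  expect_equal(dors$radial_sense, "inward")
  expect_equal(vent$handedness, "dextral")
  expect_equal(vent$radial_sense, "outward")
  sol0 <- solve_flow(shape, act, solver_config(zeta = 0, h_um = 1.5))
  d0 <- surface_swirl(sol0, "dorsal")
  v0 <- surface_swirl(sol0, "ventral")
  expect_equal(d0$handedness, "indeterminate")
  expect_equal(v0$handedness, "indeterminate")
  expect_equal(d0$radial_sense, "inward")
  expect_equal(v0$radial_sense, "outward")
})
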
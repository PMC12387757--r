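test_that("generators are seed-deterministic and carry ground truth", {
  a <- make_swirl_series(n_frames = 3, seed = 11)
  b <- make_swirl_series(n_frames = 3, seed = 11)
  c <- make_swirl_series(n_frames = 3, seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  expect_equal(attr(a, "ground_truth")$omega_deg_hr, 50)
  t1 <- make_landmark_track(seed = 4, angular_noise_sd_deg = 2)
  t2 <- make_landmark_track(seed = 4, angular_noise_sd_deg = 2)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("noiseless swirl fields are recovered to machine precision", {
  f <- make_swirl_series(omega_deg_hr = 50, v_r_um_s = -0.002,
                         noise_sd_frac = 0, n_frames = 1, seed = 1)
  d <- decompose_velocity(f)
  ok <- d$valid & is.finite(d$omega_rad_s)
  expect_equal(d$omega_rad_s[ok] * 180 / pi * 3600,
               rep(50, sum(ok)), tolerance = 1e-10)
  expect_equal(d$v_r_um_s[ok], rep(-0.002, sum(ok)), tolerance = 1e-12)
})

test_that("a peaked rotation profile appears at the right radius after binning", {
  om <- function(r) 60 * exp(-((r - 15) / 4)^2)
  f <- make_swirl_series(omega_deg_hr = om, v_r_um_s = 0, noise_sd_frac = 0,
                         n_frames = 1, domain_radius_um = 25, seed = 1)
  prof <- angular_average(decompose_velocity(f))
  i <- which.max(prof$omega_mean)
  expect_lt(abs(prof$r_mid_um[i] - 15), 1 + 1e-9)
})

test_that("solver output sampled to a grid round-trips through the PIV pipeline", {
  sol <- get_test_solution()
  f <- sample_solution_to_grid(sol, z_mode = "dorsal", spacing_um = 1)
  d <- decompose_velocity(f, r_min_um = 1)
  prof <- angular_average(d, bin_width_um = 1)
  # compare the binned azimuthal velocity against the meridional solution at
  # the same layer: clockwise-from-above flow appears as positive v_phi
  r_chk <- prof$r_mid_um[prof$n > 10 & prof$r_mid_um > 5 &
                           prof$r_mid_um < 0.9 * sol$shape$r0_um]
  h <- dorsal_height(r_chk, sol$shape)
  ref <- flow_velocity(sol, r_chk, h * 0.9)
  got <- prof$v_phi_mean[match(r_chk, prof$r_mid_um)]
  expect_gt(stats::cor(got, -ref$v_phi), 0.98)
  expect_lt(max(abs(got - (-ref$v_phi))), 0.15 * max(abs(ref$v_phi)))
})

test_that("zero chiral activity samples to a zero azimuthal grid field", {
  sol0 <- solve_flow(cell_shape(), activity_params(),
                     solver_config(zeta = 0, h_um = 1.5))
  f <- sample_solution_to_grid(sol0, z_mode = "dorsal", spacing_um = 2)
  d <- decompose_velocity(f)
  expect_lt(max(abs(d$v_phi_um_s[d$valid])), 1e-12)
})

test_that("sampled fields respect the axisymmetry of the solution", {
  sol <- get_test_solution()
  f <- sample_solution_to_grid(sol, z_mode = "dorsal", spacing_um = 2)
  # rotating the grid by 90 degrees maps (x, y) -> (-y, x) and the velocity
  # accordingly; axisymmetry makes the sampled field invariant
  key <- paste(round(f$x_um, 6), round(f$y_um, 6))
  rot_key <- paste(round(-f$y_um, 6), round(f$x_um, 6))
  m <- match(rot_key, key)
  ok <- !is.na(m) & f$valid & f$valid[m]
  expect_gt(sum(ok), 100)
  expect_equal(f$vx_um_s[m[ok]], -f$vy_um_s[ok], tolerance = 1e-9)
  expect_equal(f$vy_um_s[m[ok]], f$vx_um_s[ok], tolerance = 1e-9)
})

test_that("out-of-domain sampling layers are rejected", {
  sol <- get_test_solution()
  expect_error(sample_solution_to_grid(sol, offset_frac = 1.2), "offset_frac")
})
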
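rigid_field <- function(omega_deg_hr = 50, spacing = 1, radius = 20,
                        center = c(0, 0), vr = 0) {
  om <- omega_deg_hr * pi / 180 / 3600
  g <- seq(-radius, radius, by = spacing)
  grid <- expand.grid(x_um = g + center[1], y_um = g + center[2])
  x <- grid$x_um - center[1]; y <- grid$y_um - center[2]
  r <- pmax(sqrt(x^2 + y^2), 1e-12)
  planar_velocity_field(tibble::tibble(
    time_s = 0,
    x_um = grid$x_um, y_um = grid$y_um,
    vx_um_s = -om * y + vr * x / r,
    vy_um_s = om * x + vr * y / r,
    valid = sqrt(x^2 + y^2) <= radius
  ), center_um = center)
}

test_that("decomposition recovers rigid clockwise rotation and pure radial flow exactly", {
  f <- rigid_field(omega_deg_hr = 50)
  d <- decompose_velocity(f)
  om_deg <- d$omega_rad_s * 180 / pi * 3600
  expect_equal(om_deg[is.finite(om_deg)],
               rep(50, sum(is.finite(om_deg))), tolerance = 1e-10)
  expect_lt(max(abs(d$v_r_um_s)), 1e-14)
  k <- 0.013
  fr <- rigid_field(omega_deg_hr = 0, vr = k)
  dr <- decompose_velocity(fr)
  nz <- dr$r_um > 0
  expect_equal(dr$v_r_um_s[nz], rep(k, sum(nz)), tolerance = 1e-10)
  expect_lt(max(abs(dr$v_phi_um_s)), 1e-14)
})

test_that("the polar decomposition preserves kinetic energy pointwise and respects rotations", {
  f <- make_swirl_series(n_frames = 1, noise_sd_frac = 0.2, seed = 3)
  d <- decompose_velocity(f)
  expect_equal(d$v_phi_um_s^2 + d$v_r_um_s^2,
               d$vx_um_s^2 + d$vy_um_s^2, tolerance = 1e-10)
  # rotating the whole field about the centre leaves the radial statistics
  # unchanged
  th <- 37 * pi / 180
  rot <- tibble::tibble(
    time_s = f$time_s,
    x_um = cos(th) * f$x_um - sin(th) * f$y_um,
    y_um = sin(th) * f$x_um + cos(th) * f$y_um,
    vx_um_s = cos(th) * f$vx_um_s - sin(th) * f$vy_um_s,
    vy_um_s = sin(th) * f$vx_um_s + cos(th) * f$vy_um_s,
    valid = f$valid)
  dr <- decompose_velocity(rot, center_um = c(0, 0), r_min_um = 1)
  expect_equal(sort(dr$v_phi_um_s), sort(d$v_phi_um_s), tolerance = 1e-9)
  expect_equal(sort(dr$v_r_um_s), sort(d$v_r_um_s), tolerance = 1e-9)
})

test_that("center handling: outside-grid centres error, mask centroid recovers the centre", {
  f <- rigid_field(center = c(3, -2))
  expect_equal(mask_centroid(f), c(3, -2), tolerance = 1e-9)
  expect_error(planar_velocity_field(as.data.frame(f), center_um = c(100, 0)),
               "center")
})

test_that("temporal averaging keeps constant fields and cancels alternating ones", {
  f1 <- rigid_field()
  two <- dplyr::bind_rows(f1, dplyr::mutate(f1, time_s = 10))
  d <- decompose_velocity(planar_velocity_field(two, center_um = c(0, 0)))
  avg <- temporal_average(d)
  d1 <- decompose_velocity(f1)
  m <- match(paste(avg$x_um, avg$y_um), paste(d1$x_um, d1$y_um))
  expect_equal(avg$v_phi_um_s, d1$v_phi_um_s[m], tolerance = 1e-12)
  flip <- dplyr::mutate(f1, time_s = 10, vx_um_s = -vx_um_s, vy_um_s = -vy_um_s)
  alt <- decompose_velocity(planar_velocity_field(dplyr::bind_rows(f1, flip),
                                                  center_um = c(0, 0)))
  avg0 <- temporal_average(alt)
  expect_lt(max(abs(avg0$v_phi_um_s)), 1e-14)
  expect_error(temporal_average(d1), "2 frames")
})

test_that("angular averaging gives flat profiles for rigid rotation and honest empty bins", {
  d <- decompose_velocity(rigid_field(omega_deg_hr = 50))
  # single frame: skip temporal stage by construction
  prof <- angular_average(d, bin_width_um = 2, r_max_um = 30)
  filled <- prof[prof$n > 0 & is.finite(prof$omega_mean), ]
  expect_equal(filled$omega_mean, rep(50, nrow(filled)), tolerance = 1e-9)
  expect_true(any(prof$n == 0))   # annuli beyond the masked disc stay empty
  expect_true(all(is.na(prof$omega_mean[prof$n == 0])))
})

test_that("noisy synthetic swirl is recovered within two standard errors", {
  f <- make_swirl_series(omega_deg_hr = 50, v_r_um_s = -0.002,
                         noise_sd_frac = 0.1, n_frames = 40, seed = 2026)
  avg <- f |> decompose_velocity() |> temporal_average()
  om <- pooled_recovery(avg, "omega_rad_s")
  expect_lt(abs(om$mean * 180 / pi * 3600 - 50),
            2 * om$sem * 180 / pi * 3600)
  vr <- pooled_recovery(avg, "v_r_um_s")
  expect_lt(abs(vr$mean + 0.002), 2 * vr$sem)
})

test_that("radius rescaling divides the axis and nothing else", {
  d <- decompose_velocity(rigid_field())
  prof <- angular_average(d, bin_width_um = 1)
  sc <- rescale_radius(prof, 15)
  expect_equal(sc$r_scaled, prof$r_mid_um / 15)
  expect_equal(sc$omega_mean, prof$omega_mean)
  ident <- rescale_radius(prof, 1)
  expect_equal(ident$r_scaled, prof$r_mid_um)
  expect_error(rescale_radius(prof, 0), "positive")
})

test_that("PIV text exports round-trip through the reader", {
  f <- make_swirl_series(n_frames = 2, seed = 5, spacing_um = 2,
                         domain_radius_um = 10)
  tdir <- withr::local_tempdir()
  paths <- vapply(split(f, f$time_s), function(fr) {
    p <- tempfile(tmpdir = tdir, fileext = ".csv")
    utils::write.csv(data.frame(x = fr$x_um, y = fr$y_um, u = fr$vx_um_s,
                                v = fr$vy_um_s, mask = as.integer(fr$valid)),
                     p, row.names = FALSE)
    p
  }, character(1))
  back <- read_piv_series(paths, sort(unique(f$time_s)), center_um = c(0, 0))
  expect_equal(nrow(back), nrow(f))
  expect_equal(sort(back$vx_um_s), sort(f$vx_um_s), tolerance = 1e-12)
  expect_equal(sum(back$valid), sum(f$valid))
})
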
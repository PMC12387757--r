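test_that("closed-form derived shape matches the tangency oracle", {
  shape <- cell_shape()
  d <- shape$derived
  o <- oracle_tangent_circle(8.2, 35, 15, 22, 7 * pi / 180)
  expect_equal(d$rho1_um, o$rho1, tolerance = 1e-8)
  expect_equal(d$rho3_um, o$rho3, tolerance = 1e-8)
  expect_equal(d$r2_um, o$r2, tolerance = 1e-8)
  expect_equal(d$z2_um, o$z2, tolerance = 1e-8)
})

test_that("derived shape matches the oracle on 20 perturbed parameter sets", {
  set.seed(42)
  found <- 0
  while (found < 20) {
    f <- stats::runif(5, 0.8, 1.2)
    p <- list(z0 = 8.2 * f[1], r0 = 35 * f[2], r1 = 15 * f[3],
              rho2 = 22 * f[4], alpha = 7 * pi / 180 * f[5])
    shape <- tryCatch(
      cell_shape(z0_um = p$z0, r0_um = p$r0, r1_um = p$r1,
                 rho2_um = p$rho2, alpha_rad = p$alpha),
      error = function(e) NULL)
    if (is.null(shape)) next
    o <- oracle_tangent_circle(p$z0, p$r0, p$r1, p$rho2, p$alpha)
    expect_equal(shape$derived$rho1_um, o$rho1, tolerance = 1e-8)
    expect_equal(shape$derived$rho3_um, o$rho3, tolerance = 1e-8)
    expect_equal(shape$derived$r2_um, o$r2, tolerance = 1e-8)
    expect_equal(shape$derived$z2_um, o$z2, tolerance = 1e-8)
    found <- found + 1
  }
  expect_equal(found, 20)
})

# thin wrapper so the error tests exercise the exported derive path
derive_tangent_circle_public <- function(z0, r0, r1, rho2, alpha) {
  derive_shape(list(z0_um = z0, r0_um = r0, r1_um = r1, rho2_um = rho2,
                    alpha_rad = alpha))
}

test_that("degenerate geometries are rejected with informative errors", {
  expect_error(cell_shape(alpha_rad = 0), "alpha")
  expect_error(cell_shape(r1_um = 0), "r1_um")
  # removable alpha -> 0 singularity is rejected, not special-cased
  expect_error(derive_tangent_circle_public(8.2, 35, 15, 22, 1e-10),
               "sin")
  # parameters driving the closed-form radicand negative
  expect_error(cell_shape(r1_um = 60, z0_um = 30), "invalid geometry|ordered")
})

test_that("dorsal boundary is C0 and C1 at both junctions and hits the anchors", {
  shape <- cell_shape()
  d <- shape$derived
  expect_equal(dorsal_height(0, shape), shape$z0_um, tolerance = 1e-12)
  expect_equal(dorsal_height(shape$r0_um, shape), 0, tolerance = 1e-12)
  for (rj in c(d$rho1_um, d$rho3_um)) {
    below <- dorsal_height(rj - 1e-9, shape)
    above <- dorsal_height(rj + 1e-9, shape)
    expect_lt(abs(below - above), 1e-6 * shape$r0_um)
    s_below <- dorsal_slope(rj - 1e-7, shape)
    s_above <- dorsal_slope(rj + 1e-7, shape)
    expect_lt(abs(s_below - s_above), 1e-4)
  }
  expect_error(dorsal_height(-1, shape), "rho")
  expect_error(dorsal_height(36, shape), "rho")
})

test_that("mesh boundary tags are complete and the mesh is conforming", {
  mesh <- build_mesh(cell_shape(), h_um = 1.5)
  e <- rbind(mesh$tri[, 1:2], mesh$tri[, 2:3], mesh$tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  counts <- table(key)
  # conforming: every edge belongs to one (boundary) or two (interior) triangles
  expect_true(all(counts %in% c(1, 2)))
  bkey <- unlist(lapply(mesh$boundary, function(b) {
    paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  }))
  # each boundary edge carries exactly one tag, and tags cover precisely the
  # single-triangle edges
  expect_equal(length(bkey), length(unique(bkey)))
  expect_setequal(names(which(counts == 1)), bkey)
  # boundary nodes lie on the exact curve
  td <- tidy(mesh)
  dorsal <- td[td$boundary == "dorsal", ]
  expect_lt(max(abs(dorsal$z_um - dorsal_height(dorsal$rho_um, mesh$shape))),
            mesh$h_um^2 / mesh$shape$r0_um)
})

test_that("mesh area converges to the analytic cross-section area at order h^2", {
  shape <- cell_shape()
  exact <- cross_section_area(shape)
  ns <- c(20, 40, 80)
  errs <- vapply(ns, function(n) {
    abs(mesh_area(build_mesh(shape, h_um = 2, n_rho = n, n_z = 6)) - exact)
  }, numeric(1))
  rates <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(rates > 1.6))
})

test_that("mesh resolution outside (0, R0/10] is rejected", {
  expect_error(build_mesh(cell_shape(), h_um = 40), "meshing failure")
  expect_error(build_mesh(cell_shape(), h_um = 5), "meshing failure")
  expect_error(build_mesh(cell_shape(), h_um = -1), "meshing failure")
})
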
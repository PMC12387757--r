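# Verification by the method of manufactured solutions on a rectangular
# annular section (rho in [0.3, 1], z in [0, 0.3]), where boundary data can
# be imposed exactly on straight sides.

vphi_star <- quote(sin(2 * rho) * cos(3 * z))
# divergence-free meridional pair from the stream function rho^2 sin(rho) sin(z)
vrho_star <- quote(rho * sin(rho) * cos(z))
vz_star <- quote(-(2 * sin(rho) + rho * cos(rho)) * sin(z))
p_star <- quote(cos(2 * rho) * sin(2 * z))

test_that("manufactured forcing is the exact residual of the strong operators", {
  mf <- manufactured_forcing(vphi = vphi_star, vrho = vrho_star,
                             vz = vz_star, p = p_star)
  f <- function(e) function(r, z) eval(e, list(rho = r, z = z))
  r <- 0.62; z <- 0.17; h <- 1e-5
  lap_fd <- function(g, c_coef) {
    (g(r + h, z) - 2 * g(r, z) + g(r - h, z)) / h^2 +
      (g(r, z + h) - 2 * g(r, z) + g(r, z - h)) / h^2 +
      (g(r + h, z) - g(r - h, z)) / (2 * h) / r - c_coef * g(r, z) / r^2
  }
  expect_equal(mf$g_phi(r, z), lap_fd(f(vphi_star), 1), tolerance = 1e-6)
  expect_equal(mf$g_rho(r, z),
               lap_fd(f(vrho_star), 1) -
                 (f(p_star)(r + h, z) - f(p_star)(r - h, z)) / (2 * h),
               tolerance = 1e-6)
  expect_equal(mf$g_z(r, z),
               lap_fd(f(vz_star), 0) -
                 (f(p_star)(r, z + h) - f(p_star)(r, z - h)) / (2 * h),
               tolerance = 1e-6)
  # zero target gives zero forcing
  mf0 <- manufactured_forcing(vphi = quote(0 * rho))
  expect_equal(mf0$g_phi(0.5, 0.1), 0)
  # incompressibility violation is rejected
  expect_error(manufactured_forcing(vrho = quote(rho), vz = quote(z)),
               "incompressibility")
})

test_that("azimuthal solver converges at third order in L2", {
  mf <- manufactured_forcing(vphi = vphi_star)
  exact <- function(r, z) eval(vphi_star, list(rho = r, z = z))
  errs <- vapply(c(8, 16, 32), function(n) {
    mesh <- chiralflow:::mesh_rectangle(0.3, 1, 0.3, n, n)
    res <- solve_azimuthal(mesh, rhs = mf$g_phi, dirichlet = exact)
    chiralflow:::fem_l2_error(res$mesh, res$p2, res$vphi, exact)
  }, numeric(1))
  rates <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(rates > 2.7))
})

test_that("Stokes solver converges at the Taylor-Hood orders (3 velocity, 2 pressure)", {
  mf <- manufactured_forcing(vrho = vrho_star, vz = vz_star, p = p_star)
  errv <- c(); errp <- c()
  for (n in c(8, 16, 32)) {
    mesh <- chiralflow:::mesh_rectangle(0.3, 1, 0.3, n, n)
    res <- solve_meridional(mesh, g_rho = mf$g_rho, g_z = mf$g_z,
                            dirichlet = function(r, z) cbind(mf$vrho(r, z), mf$vz(r, z)))
    ev <- sqrt(chiralflow:::fem_l2_error(res$mesh, res$p2, res$vrho, mf$vrho)^2 +
                 chiralflow:::fem_l2_error(res$mesh, res$p2, res$vz, mf$vz)^2)
    # pressure is gauged to zero weighted mean; shift the exact field to match
    gr <- expand.grid(r = seq(0.3, 1, length.out = 80),
                      z = seq(0, 0.3, length.out = 40))
    offs <- stats::weighted.mean(mf$p(gr$r, gr$z), gr$r) -
      stats::weighted.mean(chiralflow:::eval_p1_field(res$mesh, res$p, gr$r, gr$z), gr$r)
    ep <- chiralflow:::fem_l2_error(res$mesh, res$p2, res$p + offs, mf$p, p1 = TRUE)
    errv <- c(errv, ev); errp <- c(errp, ep)
  }
  rv <- log2(errv[-length(errv)] / errv[-1])
  rp <- log2(errp[-length(errp)] / errp[-1])
  expect_true(all(rv > 2.7))
  expect_true(all(rp > 1.7))
})
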
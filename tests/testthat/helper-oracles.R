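# Shared fixtures and independent oracles.

# Brute-force tangency oracle for the shoulder-circle construction: find the
# circle with centre (rho2, Z2) tangent externally to the apical cap circle
# (centre (0, z0 - r1), radius r1) and tangent to the contact line
# z = -tan(alpha) (rho - r0), by root-finding on the tangency conditions.
# Independent of the closed form used by the package.
oracle_tangent_circle <- function(z0, r0, r1, rho2, alpha) {
  line_r2 <- function(z2) sin(alpha) * (rho2 - r0) + cos(alpha) * z2
  gap <- function(z2) {
    sqrt(rho2^2 + (z2 - (z0 - r1))^2) - r1 - line_r2(z2)
  }
  # bracket the root by scanning upward from z2 = 0
  zs <- seq(0, 50 * max(z0, r0), length.out = 20000)
  gs <- vapply(zs, gap, numeric(1))
  sgn <- which(gs[-1] * gs[-length(gs)] <= 0)
  if (!length(sgn)) stop("oracle: no tangent circle found")
  root <- stats::uniroot(gap, c(zs[sgn[1]], zs[sgn[1] + 1]), tol = 1e-13)
  z2 <- root$root
  r2 <- line_r2(z2)
  # tangency points: on the cap-centre line, and where the circle meets the line
  rho1 <- r1 * rho2 / sqrt(rho2^2 + (z2 - (z0 - r1))^2)
  rho3 <- rho2 - r2 * sin(alpha)
  list(rho1 = rho1, rho3 = rho3, r2 = r2, z2 = z2)
}

# A moderate-resolution solved flow shared by test files (built on demand,
# then cached for the session).
get_test_solution <- local({
  sol <- NULL
  function() {
    if (is.null(sol)) {
      sol <<- solve_flow(config = solver_config(h_um = 0.7))
    }
    sol
  }
})

# P2 nodes strictly inside the domain (on no boundary).
interior_p2_nodes <- function(sol) {
  setdiff(seq_len(sol$p2$n_p2), unique(unlist(sol$p2$boundary_nodes)))
}

# Pooled estimate (mean and standard error of the mean) of a quantity over
# all valid grid points of a temporally averaged decomposition.
pooled_recovery <- function(avg, col) {
  x <- avg[[col]]
  x <- x[is.finite(x)]
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}
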
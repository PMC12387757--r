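#' Solver configuration for the active chiral Stokes problem
#'
#' @param zeta Non-dimensional chiral activity, the ratio of the torque-dipole
#'   to the force-dipole stress scale over the cell radius. Default 0.004.
#' @param h_um Mesh resolution passed to [build_mesh()] (µm).
#' @param n_rho,n_z Optional explicit grid overrides.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(zeta = 0.004, h_um = 0.35, n_rho = NULL, n_z = NULL) {
  stopifnot(is.numeric(zeta), length(zeta) == 1, is.finite(zeta))
  structure(list(zeta = zeta, h_um = h_um, n_rho = n_rho, n_z = n_z),
            class = "solver_config")
}

# Uniformly scale a mesh (used to pass from micrometre to cell-radius units).
scale_mesh <- function(mesh, f) {
  mesh$nodes <- mesh$nodes * f
  mesh$rho_grid <- mesh$rho_grid * f
  mesh$heights <- mesh$heights * f
  mesh$h_um <- mesh$h_um * f
  mesh
}

# Non-dimensionalise an activity field: coordinates in units of R0,
# derivatives picking up a factor R0.
scale_field <- function(field, r0) {
  list(S = function(r, z) field$S(r * r0, z * r0),
       dSdz = function(r, z) r0 * field$dSdz(r * r0, z * r0))
}

# Velocity boundary conditions on the cell domain: no slip on the ventral
# side, v_rho = 0 on the axis, v.n = 0 with free tangential slip on the
# dorsal curve (tangential rotation of the dof pairs). Nodes shared between
# dorsal and ventral (the contact corner) keep no slip; the apex (dorsal
# meets axis) is fully fixed since the dorsal normal there is vertical.
stokes_bcs <- function(mesh, p2, shape, r0) {
  bn <- p2$boundary_nodes
  n2 <- p2$n_p2
  ventral <- bn$ventral
  axis <- setdiff(bn$axis, ventral)
  dorsal <- setdiff(bn$dorsal, ventral)
  apex <- intersect(dorsal, bn$axis)
  dorsal <- setdiff(dorsal, apex)
  fixed <- c(ventral, n2 + ventral,      # v_rho, v_z on ventral
             axis,                       # v_rho on axis
             apex, n2 + apex)            # full fix at the apex
  slope <- dorsal_slope(p2$coords[dorsal, 1] * r0, shape)
  nrm <- sqrt(1 + slope^2)
  rot <- cbind(dorsal, n2 + dorsal, 1 / nrm, slope / nrm)
  list(fixed = fixed, fixed_val = numeric(length(fixed)), rot = rot)
}

#' Solve the azimuthal (chiral) flow equation
#'
#' The azimuthal velocity decouples from the meridional problem and solves a
#' scalar elliptic equation whose right-hand side is the z-gradient of the
#' torque-dipole stress, `(zeta / rho) S dS/dz`, with no slip on the ventral
#' boundary and axis and free slip (natural flux) on the dorsal curve.
#' All quantities are non-dimensional: lengths in units of the cell radius
#' R0, velocities in units of the active velocity scale.
#'
#' @param mesh A [build_mesh()] mesh of the cell section (µm coordinates).
#' @param field An [activity_field()] list (µm-based evaluators).
#' @param zeta Non-dimensional chiral activity.
#' @param rhs Optional override of the strong right-hand side, a function of
#'   non-dimensional `(rho, z)`; used by the manufactured-solution
#'   verification. When given, `field`/`zeta` are ignored.
#' @param dirichlet Either `"cell"` (default boundary conditions above) or a
#'   function `g(rho, z)` imposed on all boundary nodes (verification mode).
#' @return A list with the P2 coefficient vector `vphi` (non-dimensional),
#'   the scaled mesh and P2 structure, and the stiffness matrix reused by
#'   diagnostics.
#' @export
solve_azimuthal <- function(mesh, field = NULL, zeta = 0.004, rhs = NULL,
                            dirichlet = "cell") {
  r0 <- if (!is.null(mesh$shape)) mesh$shape$r0_um else 1
  smesh <- scale_mesh(mesh, 1 / r0)
  p2 <- p2_structure(smesh)
  if (is.null(rhs)) {
    stopifnot(!is.null(field))
    sf <- scale_field(field, r0)
    rhs <- function(r, z) ifelse(r > 1e-13, zeta * sf$S(r, z) * sf$dSdz(r, z) / r, 0)
  }
  K <- assemble_scalar_stiffness(smesh, p2, mass_over_rho = TRUE)
  F <- assemble_scalar_load(smesh, p2, rhs)
  if (is.function(dirichlet)) {
    bnodes <- sort(unique(unlist(p2$boundary_nodes)))
    vals <- dirichlet(p2$coords[bnodes, 1], p2$coords[bnodes, 2])
    u <- solve_constrained(K, F, fixed = bnodes, fixed_val = vals)
  } else {
    bnodes <- sort(unique(c(p2$boundary_nodes$ventral, p2$boundary_nodes$axis)))
    u <- solve_constrained(K, F, fixed = bnodes,
                           fixed_val = numeric(length(bnodes)))
  }
  list(vphi = u, mesh = smesh, p2 = p2, K = K)
}

#' Solve the meridional (achiral) Stokes problem
#'
#' Solves the axisymmetric Stokes system for `(v_rho, v_z, P)` driven by the
#' radial force-dipole term `S^2 / rho`, with incompressibility, no slip on
#' the ventral boundary, `v_rho = 0` on the axis, free slip (`v.n = 0`, zero
#' tangential traction in the gradient-form weak sense) on the dorsal curve,
#' and a zero-mean pressure gauge enforced by a Lagrange multiplier. The
#' chiral activity does not enter this subproblem.
#'
#' @inheritParams solve_azimuthal
#' @param g_rho,g_z Optional overrides of the strong right-hand sides
#'   (verification mode).
#' @param dirichlet `"cell"` or a function `g(rho, z)` returning a 2-column
#'   matrix of `(v_rho, v_z)` values imposed on all boundary nodes.
#' @return A list with P2 coefficient vectors `vrho`, `vz`, P1 pressures `p`
#'   (zero weighted mean), the gauge multiplier, scaled mesh and structures.
#' @export
solve_meridional <- function(mesh, field = NULL, g_rho = NULL, g_z = NULL,
                             dirichlet = "cell") {
  r0 <- if (!is.null(mesh$shape)) mesh$shape$r0_um else 1
  smesh <- scale_mesh(mesh, 1 / r0)
  p2 <- p2_structure(smesh)
  if (is.null(g_rho)) {
    stopifnot(!is.null(field))
    sf <- scale_field(field, r0)
    g_rho <- function(r, z) ifelse(r > 1e-13, sf$S(r, z)^2 / r, 0)
  }
  sys <- assemble_stokes(smesh, p2, g_rho = g_rho, g_z = g_z)
  n2 <- sys$n2
  if (is.function(dirichlet)) {
    bnodes <- sort(unique(unlist(p2$boundary_nodes)))
    vals <- dirichlet(p2$coords[bnodes, 1], p2$coords[bnodes, 2])
    fixed <- c(bnodes, n2 + bnodes)
    fixed_val <- c(vals[, 1], vals[, 2])
    u <- solve_constrained(sys$K, sys$F, fixed = fixed, fixed_val = fixed_val)
  } else {
    bc <- stokes_bcs(smesh, p2, mesh$shape, r0)
    u <- solve_constrained(sys$K, sys$F, fixed = bc$fixed,
                           fixed_val = bc$fixed_val, rot_pairs = bc$rot)
  }
  list(vrho = u[seq_len(n2)], vz = u[n2 + seq_len(n2)],
       p = u[2 * n2 + seq_len(sys$n1)], gauge_mult = u[length(u)],
       mesh = smesh, p2 = p2, sys = sys)
}

#' Solve the full active chiral flow problem on the cell domain
#'
#' Composes [solve_azimuthal()] and [solve_meridional()] on a shared mesh and
#' returns a `flow_solution` with non-dimensional velocity fields
#' `(v_rho, v_phi, v_z)` and pressure, plus divergence and peak-speed
#' diagnostics.
#'
#' @param shape A [cell_shape()].
#' @param act An [activity_params()].
#' @param config A [solver_config()].
#' @param mesh Optionally a prebuilt [build_mesh()] mesh (overrides the
#'   resolution in `config`).
#' @return An object of class `flow_solution`.
#' @examples
#' \donttest{
#' sol <- solve_flow(cell_shape(), activity_params(), solver_config(h_um = 1))
#' glance(sol)
#' }
#' @export
solve_flow <- function(shape = cell_shape(), act = activity_params(shape),
                       config = solver_config(), mesh = NULL) {
  if (is.null(mesh)) {
    mesh <- build_mesh(shape, h_um = config$h_um,
                       n_rho = config$n_rho, n_z = config$n_z)
  }
  field <- activity_field(shape, act)
  az <- solve_azimuthal(mesh, field, zeta = config$zeta)
  mer <- solve_meridional(mesh, field)
  sol <- structure(list(
    mesh_um = mesh, mesh = az$mesh, p2 = az$p2,
    shape = shape, act = act, field = field, zeta = config$zeta,
    vphi = az$vphi, vrho = mer$vrho, vz = mer$vz, p = mer$p,
    gauge_mult = mer$gauge_mult
  ), class = "flow_solution")
  sol$diagnostics <- flow_diagnostics(sol, mer$sys)
  sol
}

# Discrete divergence (projection of div v onto the pressure space, the
# constraint actually imposed) and raw pointwise L2 divergence, both
# relative to the L2 norm of the meridional velocity; plus peak speeds.
flow_diagnostics <- function(sol, sys = NULL) {
  mesh <- sol$mesh; p2 <- sol$p2
  geo <- tri_geometry(mesh)
  q <- tri_quadrature()
  div2 <- 0; vel2 <- 0
  for (iq in seq_along(q$w)) {
    lam <- q$lambda[iq, ]
    rq <- as.numeric(geo$x %*% lam)
    w <- q$w[iq] * geo$area
    w[w < 0] <- 0
    dNl <- p2_shape_dlam(lam)
    N <- p2_shape(lam)
    vr <- 0; vz <- 0; dvr <- 0; dvz <- 0
    for (a in 1:6) {
      cf_r <- sol$vrho[p2$tri6[, a]]
      cf_z <- sol$vz[p2$tri6[, a]]
      gxa <- as.numeric(geo$gb %*% dNl[a, ])
      gza <- as.numeric(geo$gc %*% dNl[a, ])
      vr <- vr + N[a] * cf_r
      vz <- vz + N[a] * cf_z
      dvr <- dvr + gxa * cf_r
      dvz <- dvz + gza * cf_z
    }
    div_pt <- ifelse(rq > 1e-13, vr / rq, 0) + dvr + dvz
    div2 <- div2 + sum(w * rq * div_pt^2)
    vel2 <- vel2 + sum(w * rq * (vr^2 + vz^2))
  }
  disc <- NA_real_
  if (!is.null(sys)) {
    n2 <- sys$n2
    u_full <- c(sol$vrho, sol$vz, sol$p,
                if (is.null(sol$gauge_mult)) 0 else sol$gauge_mult)
    res <- as.numeric(sys$K %*% u_full - sys$F)
    cont <- res[2 * n2 + seq_len(sys$n1)]
    disc <- sqrt(sum(cont^2)) / max(sqrt(vel2), 1e-300)
  }
  speed_mer <- sqrt(sol$vrho^2 + sol$vz^2)
  list(div_l2_rel = sqrt(div2) / max(sqrt(vel2), 1e-300),
       div_discrete_rel = disc,
       peak_vphi = max(abs(sol$vphi)),
       peak_vrho = max(abs(sol$vrho)),
       peak_meridional = max(speed_mer),
       peak_speed = max(max(abs(sol$vphi)), max(speed_mer)),
       n_p2 = p2$n_p2, n_tri = nrow(mesh$tri))
}

#' @method print flow_solution
#' @export
print.flow_solution <- function(x, ...) {
  d <- x$diagnostics
  cat("<flow_solution> axisymmetric active chiral Stokes solve\n")
  cat(sprintf("  zeta = %.4g, %d P2 nodes, %d triangles\n", x$zeta, d$n_p2, d$n_tri))
  cat(sprintf("  peak |v_phi| = %.4g, peak meridional speed = %.4g (non-dim.)\n",
              d$peak_vphi, d$peak_meridional))
  cat(sprintf("  divergence: discrete %.3g, pointwise L2 %.3g (relative)\n",
              d$div_discrete_rel, d$div_l2_rel))
  invisible(x)
}

#' Evaluate a flow solution at arbitrary points
#'
#' @param sol A `flow_solution`.
#' @param rho_um,z_um Coordinates in µm (vectorised, recycled).
#' @return A tibble with `rho_um`, `z_um`, non-dimensional `v_rho`, `v_phi`,
#'   `v_z`, `pressure`, and `S`. Points outside the domain give NA.
#' @export
flow_velocity <- function(sol, rho_um, z_um) {
  stopifnot(inherits(sol, "flow_solution"))
  r0 <- sol$shape$r0_um
  n <- max(length(rho_um), length(z_um))
  rho <- rep_len(rho_um, n); z <- rep_len(z_um, n)
  loc <- locate_points(sol$mesh, rho / r0, z / r0)
  tibble::tibble(
    rho_um = rho, z_um = z,
    v_rho = eval_p2_field(sol$mesh, sol$p2, sol$vrho, rho / r0, z / r0, loc),
    v_phi = eval_p2_field(sol$mesh, sol$p2, sol$vphi, rho / r0, z / r0, loc),
    v_z = eval_p2_field(sol$mesh, sol$p2, sol$vz, rho / r0, z / r0, loc),
    pressure = eval_p1_field(sol$mesh, sol$p, rho / r0, z / r0, loc),
    S = order_parameter(rho, z, sol$shape, sol$act)
  )
}

#' @rdname flow_velocity
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return For `tidy()`: one row per P2 node with coordinates (µm), the
#'   order parameter and the non-dimensional velocity components.
#' @method tidy flow_solution
#' @export
tidy.flow_solution <- function(x, ...) {
  r0 <- x$shape$r0_um
  tibble::tibble(
    rho_um = x$p2$coords[, 1] * r0,
    z_um = x$p2$coords[, 2] * r0,
    S = order_parameter(x$p2$coords[, 1] * r0, x$p2$coords[, 2] * r0,
                        x$shape, x$act),
    v_rho = x$vrho, v_phi = x$vphi, v_z = x$vz
  )
}

#' @rdname flow_velocity
#' @method glance flow_solution
#' @export
glance.flow_solution <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    zeta = x$zeta,
    peak_vphi = d$peak_vphi,
    peak_vrho = d$peak_vrho,
    peak_meridional = d$peak_meridional,
    peak_speed = d$peak_speed,
    div_discrete_rel = d$div_discrete_rel,
    div_l2_rel = d$div_l2_rel,
    n_p2 = d$n_p2,
    n_tri = d$n_tri
  )
}

#' Export a flow solution as legacy VTK point data
#'
#' @param sol A `flow_solution`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_flow_vtk <- function(sol, path) {
  v <- sol$p2$n_vertex
  write_mesh_vtk(sol$mesh_um, path, point_data = list(
    v_rho = sol$vrho[seq_len(v)],
    v_phi = sol$vphi[seq_len(v)],
    v_z = sol$vz[seq_len(v)],
    pressure = sol$p,
    S = order_parameter(sol$mesh_um$nodes[, 1], sol$mesh_um$nodes[, 2],
                        sol$shape, sol$act)
  ))
}
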
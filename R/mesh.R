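#' Triangulate the meridional cell section
#'
#' Builds a boundary-fitted triangulation of the (rho, z) section by mapping a
#' structured grid: `n_rho` uniform columns in rho, each carrying `n_z + 1`
#' nodes spaced uniformly between the substrate and the exact dorsal curve,
#' so column nodes lie on the analytic boundary. The last column collapses
#' onto the contact point (R0, 0) as a triangle fan. The mapping naturally
#' refines the z spacing where the cell is thin, which is where the
#' actomyosin band sits.
#'
#' @param shape A [cell_shape()] object.
#' @param h_um Target edge length (µm); must satisfy `0 < h <= R0/10`.
#'   Default 0.35 µm (R0/100 for the default shape) resolves the radial
#'   activity cutoff layer (width ~1/lambda2 = 1.75 µm) with >= 5 elements.
#' @param n_rho,n_z Optionally override the number of columns / rows implied
#'   by `h_um`.
#'
#' @return An object of class `meridional_mesh`: node coordinates (µm),
#'   triangle connectivity (counter-clockwise), boundary edges tagged
#'   `ventral` (z = 0), `dorsal` (the piecewise curve), `axis` (rho = 0),
#'   and the generating grid structure.
#' @examples
#' mesh <- build_mesh(cell_shape(), h_um = 2)
#' mesh
#' @export
build_mesh <- function(shape, h_um = 0.35, n_rho = NULL, n_z = NULL) {
  stopifnot(inherits(shape, "cell_shape"))
  if (!is_pos_scalar(h_um) || h_um > shape$r0_um / 10) {
    stop(sprintf(
      "meshing failure: h_um = %.4g not in (0, R0/10] for R0 = %.4g (shape: Z0=%.3g, R0=%.3g, r1=%.3g, rho2=%.3g, alpha=%.3g)",
      h_um, shape$r0_um, shape$z0_um, shape$r0_um, shape$r1_um,
      shape$rho2_um, shape$alpha_rad))
  }
  n_rho <- if (is.null(n_rho)) max(10L, as.integer(ceiling(shape$r0_um / h_um))) else as.integer(n_rho)
  n_z <- if (is.null(n_z)) max(4L, as.integer(ceiling(shape$z0_um / h_um))) else as.integer(n_z)
  stopifnot(n_rho >= 2, n_z >= 2)

  rho_grid <- seq(0, shape$r0_um, length.out = n_rho + 1)
  heights <- dorsal_height(rho_grid, shape)
  # full columns at rho_grid[1..n_rho]; the column at R0 collapses to a point
  nid <- matrix(seq_len(n_rho * (n_z + 1)), nrow = n_rho, ncol = n_z + 1,
                byrow = TRUE)
  rho_nodes <- rep(rho_grid[seq_len(n_rho)], each = n_z + 1)
  z_nodes <- as.vector(vapply(seq_len(n_rho),
                              function(i) heights[i] * (0:n_z) / n_z,
                              numeric(n_z + 1)))
  corner <- n_rho * (n_z + 1) + 1L
  nodes <- cbind(rho = c(rho_nodes, shape$r0_um), z = c(z_nodes, 0))

  i1 <- seq_len(n_rho - 1)
  lower <- cbind(as.vector(nid[i1, 1:n_z]),
                 as.vector(nid[i1 + 1, 1:n_z]),
                 as.vector(nid[i1 + 1, 2:(n_z + 1)]))
  upper <- cbind(as.vector(nid[i1, 1:n_z]),
                 as.vector(nid[i1 + 1, 2:(n_z + 1)]),
                 as.vector(nid[i1, 2:(n_z + 1)]))
  fan <- cbind(nid[n_rho, 1:n_z], rep(corner, n_z), nid[n_rho, 2:(n_z + 1)])
  tri <- rbind(lower, upper, fan)
  colnames(tri) <- c("v1", "v2", "v3")
  nL <- (n_rho - 1) * n_z
  quad_lower <- matrix(seq_len(nL), nrow = n_rho - 1)          # [i, j]
  quad_upper <- matrix(nL + seq_len(nL), nrow = n_rho - 1)
  fan_idx <- 2L * nL + seq_len(n_z)

  boundary <- list(
    ventral = cbind(c(nid[i1, 1], nid[n_rho, 1]),
                    c(nid[i1 + 1, 1], corner)),
    dorsal = cbind(c(nid[i1, n_z + 1], nid[n_rho, n_z + 1]),
                   c(nid[i1 + 1, n_z + 1], corner)),
    axis = cbind(nid[1, 1:n_z], nid[1, 2:(n_z + 1)])
  )

  mesh <- structure(list(
    nodes = nodes, tri = tri, boundary = boundary,
    shape = shape, h_um = h_um,
    n_rho = n_rho, n_z = n_z, rho_grid = rho_grid, heights = heights,
    nid = nid, corner = corner,
    quad_lower = quad_lower, quad_upper = quad_upper, fan_idx = fan_idx
  ), class = "meridional_mesh")
  mesh
}

#' @method print meridional_mesh
#' @export
print.meridional_mesh <- function(x, ...) {
  cat(sprintf("<meridional_mesh> %d nodes, %d triangles (h = %.3g um, %d x %d grid)\n",
              nrow(x$nodes), nrow(x$tri), x$h_um, x$n_rho, x$n_z))
  cat(sprintf("  area = %.4f um^2 (analytic %.4f)\n",
              mesh_area(x), cross_section_area(x$shape)))
  invisible(x)
}

triangle_areas <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Total area of a meridional mesh
#' @param mesh A `meridional_mesh`.
#' @return Sum of signed triangle areas (µm^2).
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Node table of a meridional mesh
#'
#' @param x A `meridional_mesh`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `rho_um`, `z_um`, `boundary`
#'   (`ventral`/`dorsal`/`axis`/`interior`; the contact corner is tagged
#'   `ventral`, the apex `axis`).
#' @method tidy meridional_mesh
#' @export
tidy.meridional_mesh <- function(x, ...) {
  tag <- rep("interior", nrow(x$nodes))
  for (nm in c("dorsal", "axis", "ventral")) { # later tags take precedence
    tag[unique(as.vector(x$boundary[[nm]]))] <- nm
  }
  tibble::tibble(node = seq_len(nrow(x$nodes)),
                 rho_um = x$nodes[, 1], z_um = x$nodes[, 2], boundary = tag)
}

#' Export a mesh (and optional nodal fields) as legacy ASCII VTK
#'
#' Writes an unstructured-grid `.vtk` file readable by ParaView. Nodal
#' fields are written as POINT_DATA scalars.
#'
#' @param mesh A `meridional_mesh`.
#' @param path Output file path.
#' @param point_data Named list of numeric vectors (one value per node).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  np <- nrow(mesh$nodes); nt <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "chiralflow meridional mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", np)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nt, 4 * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", np), con)
    for (nm in names(point_data)) {
      stopifnot(length(point_data[[nm]]) == np)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.10g", point_data[[nm]])), con)
    }
  }
  invisible(path)
}

# Structured rectangle mesh on [rho_min, rho_max] x [0, height]; used by the
# manufactured-solution verification path where all four sides are tagged and
# carry Dirichlet data.
mesh_rectangle <- function(rho_min, rho_max, height, n_rho, n_z) {
  stopifnot(rho_max > rho_min, height > 0, n_rho >= 2, n_z >= 2)
  rho_grid <- seq(rho_min, rho_max, length.out = n_rho + 1)
  z_grid <- seq(0, height, length.out = n_z + 1)
  nid <- matrix(seq_len((n_rho + 1) * (n_z + 1)), nrow = n_rho + 1,
                ncol = n_z + 1, byrow = TRUE)
  nodes <- cbind(rho = rep(rho_grid, each = n_z + 1),
                 z = rep(z_grid, n_rho + 1))
  i1 <- seq_len(n_rho)
  lower <- cbind(as.vector(nid[i1, 1:n_z]),
                 as.vector(nid[i1 + 1, 1:n_z]),
                 as.vector(nid[i1 + 1, 2:(n_z + 1)]))
  upper <- cbind(as.vector(nid[i1, 1:n_z]),
                 as.vector(nid[i1 + 1, 2:(n_z + 1)]),
                 as.vector(nid[i1, 2:(n_z + 1)]))
  tri <- rbind(lower, upper)
  colnames(tri) <- c("v1", "v2", "v3")
  boundary <- list(
    ventral = cbind(nid[i1, 1], nid[i1 + 1, 1]),
    dorsal = cbind(nid[i1, n_z + 1], nid[i1 + 1, n_z + 1]),
    axis = cbind(nid[1, 1:n_z], nid[1, 2:(n_z + 1)]),
    outer = cbind(nid[n_rho + 1, 1:n_z], nid[n_rho + 1, 2:(n_z + 1)])
  )
  nL <- n_rho * n_z
  structure(list(nodes = nodes, tri = tri, boundary = boundary,
                 shape = NULL, h_um = (rho_max - rho_min) / n_rho,
                 n_rho = n_rho, n_z = n_z, rho_grid = rho_grid,
                 heights = rep(height, n_rho + 1), nid = nid, corner = NA,
                 quad_lower = matrix(seq_len(nL), nrow = n_rho),
                 quad_upper = matrix(nL + seq_len(nL), nrow = n_rho),
                 fan_idx = integer(0)),
            class = "meridional_mesh")
}
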
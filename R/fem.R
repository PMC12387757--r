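# Axisymmetric finite-element machinery: quadratic (P2) scalar fields and a
# Taylor-Hood P2/P1 Stokes saddle point on meridional triangulations.
#
# All weak forms carry the cylindrical volume weight rho drho dz (the 2*pi
# factor is dropped throughout). The azimuthal-type scalar operator is
#   a(u, w) = int rho grad u . grad w + int u w / rho,
# whose natural boundary condition is zero weighted normal flux
# rho du/dn = 0 (the free-slip reading used on the dorsal boundary).

# --- P2 node structure -------------------------------------------------------

p2_structure <- function(mesh) {
  tri <- mesh$tri
  nv <- nrow(mesh$nodes)
  e_all <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  uk <- unique(key)
  edge_id <- match(key, uk)
  first <- match(uk, key)
  edges <- cbind(pmin(e_all[first, 1], e_all[first, 2]),
                 pmax(e_all[first, 1], e_all[first, 2]))
  nt <- nrow(tri)
  tri6 <- cbind(tri,
                nv + edge_id[seq_len(nt)],
                nv + edge_id[nt + seq_len(nt)],
                nv + edge_id[2 * nt + seq_len(nt)])
  mid <- (mesh$nodes[edges[, 1], , drop = FALSE] +
            mesh$nodes[edges[, 2], , drop = FALSE]) / 2
  coords <- rbind(mesh$nodes, mid)
  edge_key <- uk
  boundary_nodes <- lapply(mesh$boundary, function(be) {
    bk <- paste(pmin(be[, 1], be[, 2]), pmax(be[, 1], be[, 2]))
    ids <- match(bk, edge_key)
    sort(unique(c(as.vector(be), nv + ids[!is.na(ids)])))
  })
  list(coords = coords, tri6 = tri6, n_vertex = nv, n_p2 = nrow(coords),
       boundary_nodes = boundary_nodes)
}

# --- reference element -------------------------------------------------------

# 7-point degree-5 Gauss rule on the reference triangle (barycentric).
tri_quadrature <- function() {
  a1 <- 0.0597158717897698; b1 <- 0.4701420641051151
  a2 <- 0.7974269853530873; b2 <- 0.1012865073234563
  lam <- rbind(c(1 / 3, 1 / 3, 1 / 3),
               c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
               c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(0.225,
         rep(0.1323941527885062, 3),
         rep(0.1259391805448272, 3))
  list(lambda = lam, w = w)
}

p2_shape <- function(lam) {
  l1 <- lam[1]; l2 <- lam[2]; l3 <- lam[3]
  c(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
    4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
}

# dN/dlambda (6 x 3) at a barycentric point
p2_shape_dlam <- function(lam) {
  l1 <- lam[1]; l2 <- lam[2]; l3 <- lam[3]
  rbind(c(4 * l1 - 1, 0, 0),
        c(0, 4 * l2 - 1, 0),
        c(0, 0, 4 * l3 - 1),
        c(4 * l2, 4 * l1, 0),
        c(0, 4 * l3, 4 * l2),
        c(4 * l3, 0, 4 * l1))
}

# Per-triangle geometry: areas and the constant gradients of the barycentric
# coordinates, vectorised over all triangles.
tri_geometry <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]
  detJ <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  gb <- cbind(y2 - y3, y3 - y1, y1 - y2) / detJ   # d lambda_i / d rho
  gc <- cbind(x3 - x2, x1 - x3, x2 - x1) / detJ   # d lambda_i / d z
  list(x = cbind(x1, x2, x3), y = cbind(y1, y2, y3),
       area = detJ / 2, gb = gb, gc = gc)
}

# --- assembly ----------------------------------------------------------------

# Scalar operator int rho grad u . grad w + mass_over_rho * int u w / rho.
assemble_scalar_stiffness <- function(mesh, p2, mass_over_rho = TRUE) {
  geo <- tri_geometry(mesh)
  q <- tri_quadrature()
  nt <- nrow(mesh$tri)
  ok <- geo$area > 1e-14 * max(geo$area)
  nq <- length(q$w)
  iL <- vector("list", nq * 36); jL <- iL; vL <- iL; k <- 0
  for (iq in seq_len(nq)) {
    lam <- q$lambda[iq, ]
    rq <- geo$x %*% lam
    w <- q$w[iq] * geo$area
    N <- p2_shape(lam)
    dNl <- p2_shape_dlam(lam)
    # gradients of the 6 basis functions at this point, per triangle
    gx <- vector("list", 6); gz <- vector("list", 6)
    for (a in 1:6) {
      gx[[a]] <- geo$gb %*% dNl[a, ]
      gz[[a]] <- geo$gc %*% dNl[a, ]
    }
    inv_r <- ifelse(rq > 1e-13, 1 / rq, 0)
    for (a in 1:6) for (b in 1:6) {
      val <- w * (rq * (gx[[a]] * gx[[b]] + gz[[a]] * gz[[b]]))
      if (mass_over_rho) val <- val + w * N[a] * N[b] * inv_r
      val[!ok] <- 0
      k <- k + 1
      iL[[k]] <- p2$tri6[, a]; jL[[k]] <- p2$tri6[, b]; vL[[k]] <- as.numeric(val)
    }
  }
  Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(vL),
                       dims = c(p2$n_p2, p2$n_p2))
}

# Load vector -int rho g(rho,z) N_a for a strong right-hand side g.
assemble_scalar_load <- function(mesh, p2, g) {
  geo <- tri_geometry(mesh)
  q <- tri_quadrature()
  ok <- geo$area > 1e-14 * max(geo$area)
  Fv <- numeric(p2$n_p2)
  for (iq in seq_along(q$w)) {
    lam <- q$lambda[iq, ]
    rq <- as.numeric(geo$x %*% lam)
    zq <- as.numeric(geo$y %*% lam)
    w <- q$w[iq] * geo$area
    w[!ok] <- 0
    gv <- g(rq, zq)
    N <- p2_shape(lam)
    for (a in 1:6) {
      contrib <- -w * rq * gv * N[a]
      s <- rowsum(contrib, p2$tri6[, a])
      idx <- as.integer(rownames(s))
      Fv[idx] <- Fv[idx] + s[, 1]
    }
  }
  Fv
}

# Taylor-Hood Stokes blocks. Unknown ordering: v_rho (P2), v_z (P2),
# P (P1 vertices), one zero-mean pressure multiplier. Momentum rows are the
# rho-weighted weak form of the vector Laplacian (gradient form); g_rho/g_z
# are the strong right-hand sides (forces per unit viscosity) beyond the
# pressure gradient.
assemble_stokes <- function(mesh, p2, g_rho = NULL, g_z = NULL) {
  geo <- tri_geometry(mesh)
  q <- tri_quadrature()
  nt <- nrow(mesh$tri)
  n2 <- p2$n_p2; n1 <- p2$n_vertex
  ok <- geo$area > 1e-14 * max(geo$area)
  iL <- list(); jL <- list(); vL <- list(); k <- 0
  push <- function(i, j, v) {
    k <<- k + 1; iL[[k]] <<- i; jL[[k]] <<- j; vL[[k]] <<- as.numeric(v)
  }
  F <- numeric(2 * n2 + n1 + 1)
  gauge <- numeric(n1)
  for (iq in seq_along(q$w)) {
    lam <- q$lambda[iq, ]
    rq <- as.numeric(geo$x %*% lam)
    zq <- as.numeric(geo$y %*% lam)
    w <- q$w[iq] * geo$area
    w[!ok] <- 0
    N <- p2_shape(lam)
    dNl <- p2_shape_dlam(lam)
    gx <- vector("list", 6); gz <- vector("list", 6)
    for (a in 1:6) {
      gx[[a]] <- as.numeric(geo$gb %*% dNl[a, ])
      gz[[a]] <- as.numeric(geo$gc %*% dNl[a, ])
    }
    inv_r <- ifelse(rq > 1e-13, 1 / rq, 0)
    # momentum blocks
    for (a in 1:6) for (b in 1:6) {
      lap <- w * rq * (gx[[a]] * gx[[b]] + gz[[a]] * gz[[b]])
      push(p2$tri6[, a], p2$tri6[, b], lap + w * N[a] * N[b] * inv_r) # A_rho
      push(n2 + p2$tri6[, a], n2 + p2$tri6[, b], lap)                 # A_z
    }
    # pressure coupling: -int P (rho dN_a/drho + N_a) and -int P rho dN_a/dz
    for (a in 1:6) for (b in 1:3) {
      brho <- -w * lam[b] * (rq * gx[[a]] + N[a])
      bz <- -w * lam[b] * rq * gz[[a]]
      push(p2$tri6[, a], 2 * n2 + mesh$tri[, b], brho)
      push(n2 + p2$tri6[, a], 2 * n2 + mesh$tri[, b], bz)
      push(2 * n2 + mesh$tri[, b], p2$tri6[, a], brho)       # continuity rows
      push(2 * n2 + mesh$tri[, b], n2 + p2$tri6[, a], bz)
    }
    # loads and pressure gauge weights
    if (!is.null(g_rho)) {
      gv <- g_rho(rq, zq)
      for (a in 1:6) {
        s <- rowsum(-w * rq * gv * N[a], p2$tri6[, a])
        idx <- as.integer(rownames(s))
        F[idx] <- F[idx] + s[, 1]
      }
    }
    if (!is.null(g_z)) {
      gv <- g_z(rq, zq)
      for (a in 1:6) {
        s <- rowsum(-w * rq * gv * N[a], p2$tri6[, a])
        idx <- n2 + as.integer(rownames(s))
        F[idx] <- F[idx] + s[, 1]
      }
    }
    for (b in 1:3) {
      s <- rowsum(w * lam[b] * rq, mesh$tri[, b])
      idx <- as.integer(rownames(s))
      gauge[idx] <- gauge[idx] + s[, 1]
    }
  }
  ng <- 2 * n2 + n1 + 1
  push(rep(ng, n1), 2 * n2 + seq_len(n1), gauge)
  push(2 * n2 + seq_len(n1), rep(ng, n1), gauge)
  K <- Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(vL),
                            dims = c(ng, ng))
  list(K = K, F = F, n2 = n2, n1 = n1)
}

# --- constrained solve -------------------------------------------------------

# Solve K u = F subject to u[fixed] = fixed_val and, for each row of
# rot_pairs = cbind(dof_a, dof_b, t_a, t_b), the constraint that (u_a, u_b)
# is parallel to (t_a, t_b) (one tangential unknown per pair).
solve_constrained <- function(K, F, fixed = integer(0),
                              fixed_val = numeric(0),
                              rot_pairs = NULL) {
  n <- length(F)
  stopifnot(length(fixed) == length(fixed_val))
  u_fix <- numeric(n)
  u_fix[fixed] <- fixed_val
  rot_dofs <- integer(0)
  if (!is.null(rot_pairs) && nrow(rot_pairs)) {
    keep <- !(rot_pairs[, 1] %in% fixed) & !(rot_pairs[, 2] %in% fixed)
    rot_pairs <- rot_pairs[keep, , drop = FALSE]
    rot_dofs <- c(rot_pairs[, 1], rot_pairs[, 2])
  }
  free <- setdiff(seq_len(n), c(fixed, rot_dofs))
  n_red <- length(free) + if (is.null(rot_pairs)) 0L else nrow(rot_pairs)
  gi <- c(free, if (!is.null(rot_pairs)) c(rot_pairs[, 1], rot_pairs[, 2]))
  gj <- c(seq_along(free),
          if (!is.null(rot_pairs)) rep(length(free) + seq_len(nrow(rot_pairs)), 2))
  gv <- c(rep(1, length(free)),
          if (!is.null(rot_pairs)) c(rot_pairs[, 3], rot_pairs[, 4]))
  G <- Matrix::sparseMatrix(i = gi, j = gj, x = gv, dims = c(n, n_red))
  rhs <- Matrix::crossprod(G, F - K %*% u_fix)
  Kred <- Matrix::crossprod(G, K %*% G)
  u_red <- Matrix::solve(Kred, rhs)
  as.numeric(G %*% u_red) + u_fix
}

# --- point location and evaluation ------------------------------------------

# Locate points in the mapped mesh; returns triangle index and barycentric
# coordinates. Points outside the closed domain (beyond a relative tolerance)
# get NA.
locate_points <- function(mesh, rho, z, tol = 1e-8) {
  n <- max(length(rho), length(z))
  rho <- rep_len(rho, n); z <- rep_len(z, n)
  rg <- mesh$rho_grid
  r_max <- rg[length(rg)]
  span <- r_max - rg[1]
  tri_idx <- rep(NA_integer_, n)
  bary <- matrix(NA_real_, n, 3)
  geo <- tri_geometry(mesh)
  has_fan <- length(mesh$fan_idx) > 0
  n_cols <- nrow(mesh$quad_lower)      # columns of full quads
  for (p in seq_len(n)) {
    r <- min(max(rho[p], rg[1]), r_max)
    i <- min(max(findInterval(r, rg), 1L), length(rg) - 1L)
    t_frac <- (r - rg[i]) / (rg[i + 1] - rg[i])
    h_loc <- (1 - t_frac) * mesh$heights[i] + t_frac * mesh$heights[i + 1]
    # the discrete dorsal surface is the chord of the analytic curve; accept
    # queries up to a small fraction of the local height above it
    if (z[p] > h_loc * 1.05 + tol * span || z[p] < -tol * span) next
    zz <- min(max(z[p], 0), h_loc)
    if (has_fan && i > n_cols) {
      # fan strip between the last full column and the contact corner
      hN <- mesh$heights[n_cols + 1]
      u <- zz * (r_max - rg[n_cols + 1]) / (max(r_max - r, 1e-300) * hN) *
        mesh$n_z
      j <- min(max(floor(u), 0), mesh$n_z - 1) + 1
      cand <- mesh$fan_idx[c(j, max(j - 1, 1), min(j + 1, mesh$n_z))]
    } else {
      i <- min(i, n_cols)
      s <- if (h_loc > 0) zz / h_loc else 0
      j <- min(max(floor(s * mesh$n_z), 0), mesh$n_z - 1) + 1
      cand <- c(mesh$quad_lower[i, j], mesh$quad_upper[i, j])
      if (j > 1) cand <- c(cand, mesh$quad_lower[i, j - 1], mesh$quad_upper[i, j - 1])
      if (j < mesh$n_z) cand <- c(cand, mesh$quad_lower[i, j + 1], mesh$quad_upper[i, j + 1])
    }
    best <- NA_integer_; best_min <- -Inf; best_lam <- NULL
    for (tt in cand) {
      det2 <- 2 * geo$area[tt]
      if (abs(det2) < 1e-300) next
      x1 <- geo$x[tt, 1]; y1 <- geo$y[tt, 1]
      x2 <- geo$x[tt, 2]; y2 <- geo$y[tt, 2]
      x3 <- geo$x[tt, 3]; y3 <- geo$y[tt, 3]
      l2 <- ((r - x1) * (y3 - y1) - (x3 - x1) * (zz - y1)) / det2
      l3 <- ((x2 - x1) * (zz - y1) - (r - x1) * (y2 - y1)) / det2
      l1 <- 1 - l2 - l3
      m <- min(l1, l2, l3)
      if (m > best_min) { best_min <- m; best <- tt; best_lam <- c(l1, l2, l3) }
      if (m >= -1e-12) break
    }
    if (!is.na(best) && best_min > -1e-6) {
      tri_idx[p] <- best
      bary[p, ] <- pmin(pmax(best_lam, 0), 1)
      bary[p, ] <- bary[p, ] / sum(bary[p, ])
    }
  }
  list(tri = tri_idx, bary = bary)
}

eval_p2_field <- function(mesh, p2, coef, rho, z, loc = NULL) {
  if (is.null(loc)) loc <- locate_points(mesh, rho, z)
  out <- rep(NA_real_, length(loc$tri))
  okp <- which(!is.na(loc$tri))
  for (p in okp) {
    N <- p2_shape(loc$bary[p, ])
    out[p] <- sum(N * coef[p2$tri6[loc$tri[p], ]])
  }
  out
}

eval_p1_field <- function(mesh, coef, rho, z, loc = NULL) {
  if (is.null(loc)) loc <- locate_points(mesh, rho, z)
  out <- rep(NA_real_, length(loc$tri))
  okp <- which(!is.na(loc$tri))
  for (p in okp) {
    out[p] <- sum(loc$bary[p, ] * coef[mesh$tri[loc$tri[p], ]])
  }
  out
}

# Gradient of a P2 field at located points; returns cbind(d/drho, d/dz).
eval_p2_grad <- function(mesh, p2, coef, rho, z, loc = NULL) {
  if (is.null(loc)) loc <- locate_points(mesh, rho, z)
  geo <- tri_geometry(mesh)
  out <- matrix(NA_real_, length(loc$tri), 2)
  okp <- which(!is.na(loc$tri))
  for (p in okp) {
    tt <- loc$tri[p]
    dNl <- p2_shape_dlam(loc$bary[p, ])
    gxa <- dNl %*% geo$gb[tt, ]
    gza <- dNl %*% geo$gc[tt, ]
    cf <- coef[p2$tri6[tt, ]]
    out[p, ] <- c(sum(gxa * cf), sum(gza * cf))
  }
  out
}

# L2 norm (rho-weighted) of the difference between a FEM field and an exact
# function; used by the manufactured-solution verification.
fem_l2_error <- function(mesh, p2, coef, exact, p1 = FALSE) {
  geo <- tri_geometry(mesh)
  q <- tri_quadrature()
  acc <- 0
  for (iq in seq_along(q$w)) {
    lam <- q$lambda[iq, ]
    rq <- as.numeric(geo$x %*% lam)
    zq <- as.numeric(geo$y %*% lam)
    w <- q$w[iq] * geo$area
    uh <- 0
    if (p1) {
      for (a in 1:3) uh <- uh + lam[a] * coef[mesh$tri[, a]]
    } else {
      N <- p2_shape(lam)
      for (a in 1:6) uh <- uh + N[a] * coef[p2$tri6[, a]]
    }
    acc <- acc + sum(w * rq * (uh - exact(rq, zq))^2)
  }
  sqrt(acc)
}
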
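# The coupling layer: indicator field (Poisson problem sourced by spread
# interface normals), the three fluid-structure interaction force
# definitions (explicit, semi-implicit, modified) and the correction force
# that constrains the artificial fluid to follow the solid.

#' Spread interface normals onto the fluid mesh
#'
#' Midpoint quadrature over the solid boundary loop: every segment
#' contributes its outward normal times its length, spread through the
#' interpolation kernel evaluated at the segment midpoint.  The result is an
#' integrated nodal vector field whose total is the closed-curve integral of
#' the normal (zero for a closed boundary).
#'
#' @param em fluid mesh.
#' @param lm solid mesh (current configuration).
#' @return n_fluid x 2 matrix `G` (integrated source), with the quadrature
#'   data as attributes.
#' @export
spread_interface_normals <- function(em, lm) {
  bn <- boundary_normals(lm)
  loc <- locate_points(em, bn$mid)
  n <- nrow(em$nodes)
  G <- matrix(0, n, 2)
  w <- bn$normal * bn$len
  for (a in 1:3) {
    ja <- em$tri[loc$elem, a]
    G[, 1] <- G[, 1] + accum(ja, loc$bary[, a] * w[, 1], n)
    G[, 2] <- G[, 2] + accum(ja, loc$bary[, a] * w[, 2], n)
  }
  G
}

# point-in-polygon (even-odd ray casting), vectorized over points
points_in_polygon <- function(pts, poly) {
  np <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- np
  for (i in seq_len(np)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# distance from each point to a closed polygon boundary
dist_to_polygon <- function(pts, poly) {
  np <- nrow(poly)
  d2min <- rep(Inf, nrow(pts))
  j <- c(2:np, 1)
  for (i in seq_len(np)) {
    p1 <- poly[i, ]; p2 <- poly[j[i], ]
    e <- p2 - p1
    L2 <- sum(e^2)
    t <- ((pts[, 1] - p1[1]) * e[1] + (pts[, 2] - p1[2]) * e[2]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (p1[1] + t * e[1])
    dy <- pts[, 2] - (p1[2] + t * e[2])
    d2min <- pmin(d2min, dx^2 + dy^2)
  }
  sqrt(d2min)
}

# P1 stiffness (Laplace) matrix of the fluid mesh
laplace_matrix <- function(em) {
  fd <- get_femdata(em)
  tri <- em$tri
  n <- nrow(em$nodes)
  trip_i <- list(); trip_j <- list(); trip_x <- list(); nt <- 0L
  for (a in 1:3) for (b in 1:3) {
    nt <- nt + 1L
    trip_i[[nt]] <- tri[, a]
    trip_j[[nt]] <- tri[, b]
    trip_x[[nt]] <- fd$area * (fd$dNx[, a] * fd$dNx[, b] +
                                 fd$dNy[, a] * fd$dNy[, b])
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(n, n))
}

#' Solve for the indicator field
#'
#' Discrete Poisson problem `laplacian(I) = div(G)` on the fluid mesh, with
#' `I` clamped to 1 at fluid nodes deep inside the solid and to 0 at nodes
#' far from it (a safety band around the interface is left free, so the
#' indicator transitions smoothly from 0 to 1 across the interface).  The
#' raw solution may over/undershoot by a small epsilon; it is clipped to
#' `[0, 1]` and the overshoot recorded.
#'
#' @param em fluid mesh.
#' @param lm solid mesh (current configuration defines the interface).
#' @param band half-width of the unclamped transition band (cm); defaults to
#'   1.5 fluid element sizes.
#' @return nodal indicator vector with attributes `clip_eps` (largest
#'   overshoot removed by clipping) and `deep`/`far` (the clamped node sets).
#' @export
solve_indicator <- function(em, lm, band = NULL) {
  if (is.null(band)) band <- 1.5 * mesh_h(em$nodes, em$tri)
  loops <- lm$loops %||% list(lm$boundary)
  pts <- em$nodes
  inside <- rep(FALSE, nrow(pts))
  d <- rep(Inf, nrow(pts))
  for (loop in loops) {
    poly <- lm$cur[loop, , drop = FALSE]
    inside <- inside | points_in_polygon(pts, poly)
    d <- pmin(d, dist_to_polygon(pts, poly))
  }
  deep <- which(inside & d > band)
  far <- which(!inside & d > band)
  if (!length(far) && !length(deep))
    stop("configuration error: no nodes to clamp for the indicator solve")
  G <- spread_interface_normals(em, lm)
  lump <- get_lumped(em)
  Gt <- G / lump                        # nodal field from integrated source
  fd <- get_femdata(em)
  tri <- em$tri
  n <- nrow(pts)
  gx <- rowMeans(matrix(Gt[tri, 1], ncol = 3))
  gy <- rowMeans(matrix(Gt[tri, 2], ncol = 3))
  b <- numeric(n)
  for (a in 1:3)
    b <- b + accum(tri[, a], fd$area * (gx * fd$dNx[, a] + gy * fd$dNy[, a]),
                   n)
  L <- laplace_matrix(em)
  idx <- c(deep, far)
  val <- c(rep(1, length(deep)), rep(0, length(far)))
  I <- constrained_solve(L, b, idx, val)
  eps <- max(0, max(I) - 1, -min(I))
  I <- pmin(pmax(I, 0), 1)
  attr(I, "clip_eps") <- eps
  attr(I, "deep") <- deep
  attr(I, "far") <- far
  I
}

#' Fluid stress divergence evaluated at the solid nodes
#'
#' The fluid velocity and pressure are kernel-interpolated to the solid
#' nodes, the Newtonian stress `-p I + mu (grad v + grad v^T)` is formed on
#' the solid elements (current configuration) and recovered to the solid
#' nodes (lumped L2 projection); the divergence of the recovered linear
#' stress field then gives smooth integrated nodal loads
#' `f_a = sum_e (A_e/3) div(sigma)_e`.  The recovery keeps only the volume
#' term of the divergence: the fluid stress is a smooth field across the
#' immersed boundary, so no surface (traction-jump) term belongs to it —
#' evaluating it by integration by parts instead would create an artificial
#' ring of interface forces out of the smooth pressure field.
#'
#' @param em fluid mesh; @param state fluid state; @param props fluid
#'   properties; @param kernel coupling kernel; @param lm solid mesh.
#' @param include_pressure include the interpolated pressure in sigma^f;
#'   off by default because the shared incompressibility pressure cancels
#'   in the stress mismatch.
#' @return n_solid x 2 nodal loads (dyn per unit depth).
#' @export
fluid_stress_divergence_at_solid <- function(em, state, props, kernel, lm,
                                             include_pressure = FALSE) {
  v_s <- interpolate_to_solid(kernel, state$v)
  fd <- fem_element_data(lm$cur, lm$tri)
  tri <- lm$tri
  ns <- nrow(lm$cur)
  ux <- rowSums(fd$dNx * matrix(v_s[tri, 1], ncol = 3))
  uy <- rowSums(fd$dNy * matrix(v_s[tri, 1], ncol = 3))
  vx <- rowSums(fd$dNx * matrix(v_s[tri, 2], ncol = 3))
  vy <- rowSums(fd$dNy * matrix(v_s[tri, 2], ncol = 3))
  pbar <- if (include_pressure)
    rowMeans(matrix(interpolate_to_solid(kernel, state$p)[tri], ncol = 3))
  else 0
  sig <- cbind(-pbar + 2 * props$mu * ux,
               -pbar + 2 * props$mu * vy,
               props$mu * (uy + vx))
  # lumped L2 recovery of the element stress to nodes
  lump <- lumped_areas(lm$cur, lm$tri)
  sign <- matrix(0, ns, 3)
  for (a in 1:3) for (k in 1:3)
    sign[, k] <- sign[, k] + accum(tri[, a], fd$area / 3 * sig[, k], ns)
  sign <- sign / lump
  # divergence of the recovered (piecewise-linear) stress, as nodal loads
  dsx <- rowSums(fd$dNx * matrix(sign[tri, 1], ncol = 3)) +
    rowSums(fd$dNy * matrix(sign[tri, 3], ncol = 3))
  dsy <- rowSums(fd$dNx * matrix(sign[tri, 3], ncol = 3)) +
    rowSums(fd$dNy * matrix(sign[tri, 2], ncol = 3))
  fx <- fy <- numeric(ns)
  for (a in 1:3) {
    fx <- fx + accum(tri[, a], fd$area / 3 * dsx, ns)
    fy <- fy + accum(tri[, a], fd$area / 3 * dsy, ns)
  }
  cbind(fx, fy)
}

#' Explicit IFEM interaction force
#'
#' The original interaction force on solid nodes,
#' `f = -(rho_s - rho_f) a + (div sigma_s - div sigma_f) + (rho_s - rho_f) g`,
#' with all terms evaluated from the previous step (explicit coupling).
#' Divergence terms are integrated nodal loads; the inertia and gravity
#' terms are scaled by the lumped nodal areas (volumes per unit depth).
#'
#' @param lm solid mesh.
#' @param mat solid material.
#' @param sigma_s solid element stress (m x 3).
#' @param div_sigma_f_s fluid stress divergence at the solid nodes
#'   ([fluid_stress_divergence_at_solid()]), n x 2 loads.
#' @param accel estimated solid nodal acceleration (n x 2, cm/s^2).
#' @param rho_f fluid density.
#' @param g body acceleration (length 2).
#' @return n x 2 nodal forces `f^FSI,s`.
#' @export
fsi_force_explicit <- function(lm, mat, sigma_s, div_sigma_f_s, accel,
                               rho_f, g = c(0, 0)) {
  ms <- lumped_areas(lm$ref, lm$tri)
  drho <- mat$rho - rho_f
  cur <- mat$kind == "mooney-rivlin"   # Cauchy stress lives on current config
  fs <- internal_force(lm, sigma_s, current = cur) - div_sigma_f_s
  fs[, 1] <- fs[, 1] - drho * accel[, 1] * ms + drho * g[1] * ms
  fs[, 2] <- fs[, 2] - drho * accel[, 2] * ms + drho * g[2] * ms
  fs
}

#' Semi-implicit interaction force
#'
#' Only the internal force mismatch `div sigma_s - div sigma_f`; inertia and
#' gravity are carried by the effective-density momentum equation instead.
#'
#' @inheritParams fsi_force_explicit
#' @param current integrate on the current configuration (finite-strain
#'   material kinds).
#' @return n x 2 nodal forces.
#' @export
fsi_force_semi_implicit <- function(lm, sigma_s, div_sigma_f_s,
                                    current = FALSE) {
  internal_force(lm, sigma_s, current = current) - div_sigma_f_s
}

#' Material derivative of the fluid velocity, as a nodal fluid field
#'
#' `Dv/Dt = dv/dt + (v . grad) v` with the time part from two consecutive
#' states and the convective part evaluated element-wise and projected to
#' nodes with the lumped mass.
#'
#' @param em fluid mesh; @param state,state_prev consecutive fluid states;
#' @param dt time step between them.
#' @return n x 2 nodal field (cm/s^2).
#' @export
fluid_material_derivative <- function(em, state, state_prev, dt) {
  fd <- get_femdata(em)
  tri <- em$tri
  n <- nrow(em$nodes)
  v <- state$v
  dvdt <- (state$v - state_prev$v) / dt
  wx <- rowMeans(matrix(v[tri, 1], ncol = 3))
  wy <- rowMeans(matrix(v[tri, 2], ncol = 3))
  convx <- wx * rowSums(fd$dNx * matrix(v[tri, 1], ncol = 3)) +
    wy * rowSums(fd$dNy * matrix(v[tri, 1], ncol = 3))
  convy <- wx * rowSums(fd$dNx * matrix(v[tri, 2], ncol = 3)) +
    wy * rowSums(fd$dNy * matrix(v[tri, 2], ncol = 3))
  lump <- get_lumped(em)
  cx <- cy <- numeric(n)
  for (a in 1:3) {
    cx <- cx + accum(tri[, a], fd$area / 3 * convx, n)
    cy <- cy + accum(tri[, a], fd$area / 3 * convy, n)
  }
  dvdt + cbind(cx / lump, cy / lump)
}

#' Correction force of the modified IFEM
#'
#' `f = rho_s (Dv_s/Dt - Dv_f/Dt)` per solid node, scaled by the lumped
#' nodal areas into integrated loads.  It vanishes when the artificial fluid
#' follows the solid exactly; adding it to the interaction force drives the
#' overlapped fluid towards the solid velocity.
#'
#' @param lm solid mesh; @param mat material (provides rho_s).
#' @param dvs_dt solid material acceleration (n x 2).
#' @param dvf_dt_s fluid material derivative interpolated to solid nodes
#'   (n x 2).
#' @return n x 2 nodal forces.
#' @export
correction_force <- function(lm, mat, dvs_dt, dvf_dt_s) {
  ms <- lumped_areas(lm$ref, lm$tri)
  cbind(mat$rho * (dvs_dt[, 1] - dvf_dt_s[, 1]) * ms,
        mat$rho * (dvs_dt[, 2] - dvf_dt_s[, 2]) * ms)
}

#' Modified (mIFEM) interaction force
#'
#' The semi-implicit force plus the correction force:
#' `f = div sigma_s - div sigma_f + f_dv`.
#'
#' @inheritParams fsi_force_semi_implicit
#' @param f_dv correction force ([correction_force()]).
#' @return n x 2 nodal forces.
#' @export
fsi_force_modified <- function(lm, sigma_s, div_sigma_f_s, f_dv) {
  fsi_force_semi_implicit(lm, sigma_s, div_sigma_f_s) + f_dv
}

#' Coupling-error diagnostic ratios
#'
#' The terms of the explicit interaction force each contribute a coupling
#' error proportional to a property ratio: the density ratio
#' `rho_s/rho_f - 1`, the stiffness ratio `K/rho_f` (explicit) or `K/rho_s`
#' (semi-implicit, where the effective density replaces the fluid density in
#' the overlap), and the gravity ratio `(rho_s/rho_f - 1) |g|`.  The
#' predicted error magnitude scales with `dt`.
#'
#' @param mat solid material; @param props fluid properties; @param dt time
#'   step; @param semi_implicit use the semi-implicit stiffness ratio.
#' @return named list of ratios and the dt-scaled predicted error magnitude.
#' @export
coupling_error_estimate <- function(mat, props, dt, semi_implicit = FALSE) {
  density_ratio <- mat$rho / props$rho - 1
  stiffness_ratio <- if (semi_implicit) mat$K / mat$rho else mat$K / props$rho
  gravity_ratio <- density_ratio * sqrt(sum(props$g^2))
  list(density_ratio = density_ratio,
       stiffness_ratio = stiffness_ratio,
       gravity_ratio = gravity_ratio,
       predicted_error = dt * (abs(density_ratio) + stiffness_ratio +
                                 abs(gravity_ratio)))
}
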
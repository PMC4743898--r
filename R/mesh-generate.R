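# Parametric demo geometries.  All generators take physical dimensions in the
# units stated per function and return meshes in cm (internal CGS units).

# structured-grid triangles for an (ns+1) x (nt+1) node lattice given the node
# index matrix idx[i, j]; consistent diagonal orientation
grid_triangles <- function(idx) {
  ns <- nrow(idx) - 1L; nt <- ncol(idx) - 1L
  i <- rep(seq_len(ns), nt)
  j <- rep(seq_len(nt), each = ns)
  a <- idx[cbind(i, j)]
  b <- idx[cbind(i + 1L, j)]
  c_ <- idx[cbind(i + 1L, j + 1L)]
  d <- idx[cbind(i, j + 1L)]
  rbind(cbind(a, b, c_), cbind(a, c_, d))
}

#' Rectangular channel mesh
#'
#' Structured triangulation of a `length` x `height` rectangle with boundary
#' tags `inlet` (x = x0), `outlet` (x = x0 + length) and `wall` (bottom and
#' top).  Used as the test harness for analytic flows (Poiseuille, uniform
#' advection) and as the airway channel of the fold case.
#'
#' @param length,height channel dimensions (cm), must be positive.
#' @param h target element size (cm).
#' @param x0,y0 lower-left corner (cm).
#' @return an [eulerian_mesh()].
#' @export
generate_channel_mesh <- function(length, height, h, x0 = 0, y0 = 0) {
  if (length <= 0 || height <= 0 || h <= 0)
    stop("configuration error: channel dimensions and h must be positive")
  nx <- max(2L, as.integer(round(length / h)))
  ny <- max(2L, as.integer(round(height / h)))
  xs <- seq(x0, x0 + length, length.out = nx + 1L)
  ys <- seq(y0, y0 + height, length.out = ny + 1L)
  nodes <- cbind(rep(xs, ny + 1L), rep(ys, each = nx + 1L))
  idx <- matrix(seq_len((nx + 1L) * (ny + 1L)), nx + 1L, ny + 1L)
  tri <- grid_triangles(idx)
  # boundary edges with tags
  left  <- cbind(idx[1L, 1:ny], idx[1L, 2:(ny + 1L)])
  right <- cbind(idx[nx + 1L, 1:ny], idx[nx + 1L, 2:(ny + 1L)])
  bot   <- cbind(idx[1:nx, 1L], idx[2:(nx + 1L), 1L])
  top   <- cbind(idx[1:nx, ny + 1L], idx[2:(nx + 1L), ny + 1L])
  be <- data.frame(
    n1 = c(left[, 1], right[, 1], bot[, 1], top[, 1]),
    n2 = c(left[, 2], right[, 2], bot[, 2], top[, 2]),
    tag = rep(c("inlet", "outlet", "wall", "wall"),
              c(ny, ny, nx, nx)),
    stringsAsFactors = FALSE)
  eulerian_mesh(nodes, tri, be)
}

#' Disc (cell) mesh
#'
#' "Spiderweb" triangulation of a disc: a centre node surrounded by `nr`
#' concentric rings, ring k carrying 6k nodes, giving near-equilateral
#' elements of size about `h`.  Boundary nodes lie exactly on the circle.
#'
#' @param center numeric length 2 (cm).
#' @param radius disc radius (cm), positive.
#' @param h target element size (cm), must satisfy `h < radius`.
#' @return a [lagrangian_mesh()] whose boundary loop is the outer ring.
#' @export
generate_disc_mesh <- function(center, radius, h) {
  if (radius <= 0) stop("configuration error: radius must be positive")
  if (h >= radius) stop("configuration error: h must be smaller than radius")
  nr <- max(2L, as.integer(round(radius / h)))
  pts <- matrix(c(center[1], center[2]), 1L, 2L)
  ring_start <- integer(nr)  # index of first node of ring k
  for (k in seq_len(nr)) {
    m <- 6L * k
    th <- 2 * pi * (seq_len(m) - 1L) / m
    rk <- radius * k / nr
    ring_start[k] <- nrow(pts) + 1L
    pts <- rbind(pts, cbind(center[1] + rk * cos(th),
                            center[2] + rk * sin(th)))
  }
  tri <- matrix(0L, 0L, 3L)
  # innermost ring: fan around the centre
  inner <- ring_start[1] + 0:5
  for (j in 0:5)
    tri <- rbind(tri, c(1L, inner[j + 1L], inner[(j + 1L) %% 6L + 1L]))
  if (nr >= 2L) for (k in 2:nr) {
    mi <- 6L * (k - 1L); mo <- 6L * k
    inn <- ring_start[k - 1L] + 0:(mi - 1L)
    out <- ring_start[k] + 0:(mo - 1L)
    for (s in 0:5) {
      # sector s: inner nodes s*(k-1) .. (s+1)*(k-1), outer s*k .. (s+1)*k
      for (j in 0:(k - 1L)) {
        o1 <- out[(s * k + j) %% mo + 1L]
        o2 <- out[(s * k + j + 1L) %% mo + 1L]
        ii <- inn[(s * (k - 1L) + j) %% mi + 1L]
        tri <- rbind(tri, c(o1, o2, ii))
      }
      for (j in seq_len(k - 1L) - 1L) {
        i1 <- inn[(s * (k - 1L) + j) %% mi + 1L]
        i2 <- inn[(s * (k - 1L) + j + 1L) %% mi + 1L]
        o2 <- out[(s * k + j + 1L) %% mo + 1L]
        tri <- rbind(tri, c(i1, o2, i2))
      }
    }
  }
  boundary <- ring_start[nr] + 0:(6L * nr - 1L)
  lagrangian_mesh(pts, tri, boundary = boundary)
}

# --- bifurcation ----------------------------------------------------------

#' Bifurcation geometry parameters
#'
#' Parametric description of a symmetric or asymmetric planar vessel
#' bifurcation: a mother vessel of diameter `w0` splitting into two daughter
#' branches at angles `beta1` (up) and `beta2` (down) with diameters `w1`,
#' `w2` set from the diameter ratio `r_d = w1/w2` and a total-width rule
#' `w1 + w2 = width_sum_factor * w0`.  The default factor 1.8 reflects the
#' growth of total lumen cross-section across microvascular branch
#' generations and keeps both daughters passable for a cell sized to the
#' mother vessel.  Fillet radii `r0` (apex), `r1`, `r2` (outer corners)
#' smooth the branching transition.
#'
#' @param w0 mother vessel diameter (micrometres).
#' @param r_d diameter ratio w1/w2.
#' @param beta1,beta2 branch angles (radians).
#' @param r0,r1,r2 fillet radii (micrometres).
#' @param mother_len,daughter_len vessel lengths (micrometres).
#' @param h target element size (micrometres).
#' @param width_sum_factor total daughter width as a fraction of `w0`.
#' @export
bifurcation_geometry <- function(w0 = 8, r_d = 1, beta1 = pi / 4,
                                 beta2 = pi / 4, r0 = 3, r1 = 3, r2 = 3,
                                 mother_len = 14, daughter_len = 12, h = 0.8,
                                 width_sum_factor = 1.8) {
  if (w0 <= 0 || r_d <= 0 || h <= 0 || r0 < 0 || r1 < 0 || r2 < 0)
    stop("configuration error: bifurcation parameters must be positive")
  if (mother_len <= 0 || daughter_len <= 0)
    stop("configuration error: vessel lengths must be positive")
  if (beta1 <= 0 || beta2 <= 0 || beta1 + beta2 >= pi)
    stop("configuration error: branch angles infeasible")
  w2 <- width_sum_factor * w0 / (1 + r_d)
  w1 <- r_d * w2
  structure(list(w0 = w0, w1 = w1, w2 = w2, r_d = r_d,
                 beta1 = beta1, beta2 = beta2, r0 = r0, r1 = r1, r2 = r2,
                 mother_len = mother_len, daughter_len = daughter_len, h = h),
            class = "bifurcation_geometry")
}

# fillet between two rays leaving corner V along unit vectors u1, u2;
# returns tangent points, centre and a sampler of the arc from T1 to T2
corner_fillet <- function(V, u1, u2, r) {
  ct <- sum(u1 * u2)
  theta <- acos(max(-1, min(1, ct)))
  if (theta < 1e-9 || theta > pi - 1e-9)
    stop("configuration error: degenerate corner for fillet")
  tdist <- r / tan(theta / 2)
  cdist <- r / sin(theta / 2)
  w <- (u1 + u2); w <- w / sqrt(sum(w^2))
  T1 <- V + tdist * u1
  T2 <- V + tdist * u2
  C <- V + cdist * w
  a1 <- atan2(T1[2] - C[2], T1[1] - C[1])
  a2 <- atan2(T2[2] - C[2], T2[1] - C[1])
  # shorter arc from T1 to T2
  da <- a2 - a1
  if (da > pi) da <- da - 2 * pi
  if (da < -pi) da <- da + 2 * pi
  arc_len <- abs(da) * r
  sample <- function(t) {
    ang <- a1 + t * da
    cbind(C[1] + r * cos(ang), C[2] + r * sin(ang))
  }
  list(T1 = T1, T2 = T2, C = C, sample = sample, len = arc_len, da = da,
       a1 = a1)
}

seg_sampler <- function(P, Q) {
  force(P); force(Q)
  list(sample = function(t) cbind(P[1] + t * (Q[1] - P[1]),
                                  P[2] + t * (Q[2] - P[2])),
       len = sqrt(sum((Q - P)^2)))
}

# sample a chain of pieces (each with $sample and $len) with given interval
# counts per piece; returns (sum(counts)+1) x 2 points
sample_chain <- function(pieces, counts) {
  out <- NULL
  for (i in seq_along(pieces)) {
    t <- seq(0, 1, length.out = counts[i] + 1L)
    p <- pieces[[i]]$sample(t)
    if (!is.null(out)) p <- p[-1L, , drop = FALSE]
    out <- rbind(out, p)
  }
  out
}

# Coons transfinite patch: S, N are (ns+1) x 2; W, E are (nt+1) x 2;
# corners must agree: S[1]=W[1], S[end]=E[1], N[1]=W[end], N[end]=E[end]
coons_patch <- function(S, N, W, E) {
  ns <- nrow(S) - 1L; nt <- nrow(W) - 1L
  xi <- seq(0, 1, length.out = ns + 1L)
  eta <- seq(0, 1, length.out = nt + 1L)
  nodes <- matrix(0, (ns + 1L) * (nt + 1L), 2L)
  idx <- matrix(seq_len((ns + 1L) * (nt + 1L)), ns + 1L, nt + 1L)
  for (j in seq_len(nt + 1L)) {
    e <- eta[j]
    for (d in 1:2) {
      ruled <- (1 - e) * S[, d] + e * N[, d]
      lat <- (1 - xi) * W[j, d] + xi * E[j, d]
      corr <- (1 - xi) * (1 - e) * S[1, d] + xi * (1 - e) * S[ns + 1L, d] +
        (1 - xi) * e * N[1, d] + xi * e * N[ns + 1L, d]
      nodes[idx[, j], d] <- ruled + lat - corr
    }
  }
  list(nodes = nodes, tri = grid_triangles(idx), idx = idx)
}

# map each row key to the index of its first occurrence (node merging)
map_to_first <- function(key, first) {
  ids <- integer(length(key))
  ids[first] <- seq_len(sum(first))
  ids[!first] <- ids[first][match(key[!first], key[first])]
  ids
}

#' Generate a bifurcated-vessel fluid mesh
#'
#' Multi-block transfinite triangulation of the bifurcation described by a
#' [bifurcation_geometry()]: a structured mother-vessel block and one Coons
#' patch per daughter branch, with fillet arcs at the apex and the outer
#' corners.  Boundary tags: `inlet`, `outlet1` (upper daughter), `outlet2`
#' (lower daughter), `wall`.
#'
#' @param geom a `bifurcation_geometry` (micrometre units).
#' @return an [eulerian_mesh()] in cm, carrying attributes `apex_x` (cm) and
#'   `geom`.
#' @export
generate_bifurcation_mesh <- function(geom) {
  stopifnot(inherits(geom, "bifurcation_geometry"))
  g <- geom
  d1 <- c(cos(g$beta1), sin(g$beta1))
  d2 <- c(cos(g$beta2), -sin(g$beta2))
  n1v <- c(-sin(g$beta1), cos(g$beta1))   # unit normal of daughter 1
  n2v <- c(sin(g$beta2), cos(g$beta2))    # unit normal of daughter 2
  # outer corner, top: mother wall y = w0/2 meets daughter-1 upper wall
  s_top <- (g$w0 / 2 - (g$w1 / 2) * cos(g$beta1)) / sin(g$beta1)
  V_top <- s_top * d1 + (g$w1 / 2) * n1v
  s_bot <- (g$w0 / 2 - (g$w2 / 2) * cos(g$beta2)) / sin(g$beta2)
  V_bot <- s_bot * d2 - (g$w2 / 2) * n2v
  if (s_top <= 0 || s_bot <= 0)
    stop("configuration error: branches overlap (daughter wider than mother)")
  f_top <- corner_fillet(V_top, c(-1, 0), d1, g$r1)
  f_bot <- corner_fillet(V_bot, c(-1, 0), d2, g$r2)
  # apex: daughter-1 lower wall meets daughter-2 upper wall
  # L1: -(w1/2) n1v + s d1 ;  L2: (w2/2) n2v + t d2
  A <- cbind(d1, -d2)
  rhs <- (g$w2 / 2) * n2v + (g$w1 / 2) * n1v
  st <- solve(A, rhs)
  V_apex <- -(g$w1 / 2) * n1v + st[1] * d1
  f_apex <- corner_fillet(V_apex, d1, d2, g$r0)
  M0 <- f_apex$C - g$r0 * (f_apex$C - V_apex) / sqrt(sum((f_apex$C - V_apex)^2))
  # mother block extent
  x_j <- min(f_top$T1[1], f_bot$T1[1], M0[1]) - max(g$h, 0.25)
  x_in <- -g$mother_len
  if (x_j <= x_in + g$h)
    stop("configuration error: mother vessel too short for the junction")
  # seam split point on the mother outlet cross-section
  y_c <- max(-g$w0 / 4, min(g$w0 / 4, M0[2]))
  C_pt <- c(x_j, y_c)
  A_pt <- c(x_j, g$w0 / 2)
  B_pt <- c(x_j, -g$w0 / 2)
  # cross-section interval counts
  n1 <- max(3L, as.integer(round((g$w0 / 2 - y_c) / g$h)))
  n2 <- max(3L, as.integer(round((g$w0 / 2 + y_c) / g$h)))
  # daughter end cross-sections
  end1c <- d1 * (st[1] + g$daughter_len)
  end2c <- d2 * (st[2] + g$daughter_len)
  E1o <- end1c + (g$w1 / 2) * n1v; E1i <- end1c - (g$w1 / 2) * n1v
  E2o <- end2c - (g$w2 / 2) * n2v; E2i <- end2c + (g$w2 / 2) * n2v
  # --- block D1 (upper daughter) ---
  seam1 <- seg_sampler(C_pt, M0)
  arc1 <- local({            # upper half of apex arc: M0 -> T1 reversed
    f <- f_apex
    # arc parameter of M0
    aM <- atan2(M0[2] - f$C[2], M0[1] - f$C[1])
    tM <- ((aM - f$a1) %% (2 * pi))
    tM2 <- if (f$da >= 0) tM / f$da else (tM - 2 * pi) / f$da
    # sample from M0 back to T1 (t from tM2 to 0)
    list(sample = function(t) f$sample(tM2 * (1 - t)), len = abs(tM2) * f$len)
  })
  wall1i <- seg_sampler(f_apex$T1, E1i)
  n_seam <- max(2L, as.integer(round(seam1$len / g$h)))
  n_arc1 <- max(2L, as.integer(round(arc1$len / g$h)))
  n_w1 <- max(3L, as.integer(round(wall1i$len / g$h)))
  S1 <- sample_chain(list(seam1, arc1, wall1i), c(n_seam, n_arc1, n_w1))
  ns1 <- nrow(S1) - 1L
  northN1 <- list(seg_sampler(A_pt, f_top$T1),
                  list(sample = f_top$sample, len = f_top$len),
                  seg_sampler(f_top$T2, E1o))
  lenN1 <- vapply(northN1, function(p) p$len, 0)
  cN1 <- pmax(1L, as.integer(round(ns1 * lenN1 / sum(lenN1))))
  cN1[3] <- ns1 - cN1[1] - cN1[2]
  if (cN1[3] < 1L) stop("configuration error: daughter too short")
  N1 <- sample_chain(northN1, cN1)
  W1 <- sample_chain(list(seg_sampler(C_pt, A_pt)), n1)
  E1 <- sample_chain(list(seg_sampler(E1i, E1o)), n1)
  B1 <- coons_patch(S1, N1, W1, E1)
  # --- block D2 (lower daughter) ---
  arc2 <- local({            # lower half of apex arc: M0 -> T2
    f <- f_apex
    aM <- atan2(M0[2] - f$C[2], M0[1] - f$C[1])
    tM <- ((aM - f$a1) %% (2 * pi))
    tM2 <- if (f$da >= 0) tM / f$da else (tM - 2 * pi) / f$da
    list(sample = function(t) f$sample(tM2 + t * (1 - tM2)),
         len = abs(1 - tM2) * f$len)
  })
  wall2i <- seg_sampler(f_apex$T2, E2i)
  n_arc2 <- max(2L, as.integer(round(arc2$len / g$h)))
  n_w2 <- max(3L, as.integer(round(wall2i$len / g$h)))
  S2 <- sample_chain(list(seam1, arc2, wall2i), c(n_seam, n_arc2, n_w2))
  ns2 <- nrow(S2) - 1L
  southN2 <- list(seg_sampler(B_pt, f_bot$T1),
                  list(sample = f_bot$sample, len = f_bot$len),
                  seg_sampler(f_bot$T2, E2o))
  lenS2 <- vapply(southN2, function(p) p$len, 0)
  cS2 <- pmax(1L, as.integer(round(ns2 * lenS2 / sum(lenS2))))
  cS2[3] <- ns2 - cS2[1] - cS2[2]
  if (cS2[3] < 1L) stop("configuration error: daughter too short")
  N2 <- sample_chain(southN2, cS2)   # outer wall of lower daughter
  W2 <- sample_chain(list(seg_sampler(B_pt, C_pt)), n2)
  E2 <- sample_chain(list(seg_sampler(E2o, E2i)), n2)
  # block D2: south = outer wall (B_pt..E2o), north = seam+arc (C_pt..E2i)
  B2 <- coons_patch(N2, S2, W2, E2)
  # --- mother block ---
  nm <- max(3L, as.integer(round((x_j - x_in) / g$h)))
  xs <- seq(x_in, x_j, length.out = nm + 1L)
  ys <- c(seq(-g$w0 / 2, y_c, length.out = n2 + 1L),
          seq(y_c, g$w0 / 2, length.out = n1 + 1L)[-1L])
  nodesM <- cbind(rep(xs, length(ys)), rep(ys, each = nm + 1L))
  idxM <- matrix(seq_len((nm + 1L) * length(ys)), nm + 1L, length(ys))
  triM <- grid_triangles(idxM)
  # --- merge blocks ---
  allnodes <- rbind(nodesM, B1$nodes, B2$nodes)
  offs <- c(0L, nrow(nodesM), nrow(nodesM) + nrow(B1$nodes))
  alltri <- rbind(triM,
                  B1$tri + offs[2], B2$tri + offs[3])
  scale <- max(abs(allnodes))
  key <- paste(round(allnodes[, 1] / (1e-7 * scale)),
               round(allnodes[, 2] / (1e-7 * scale)))
  ids <- map_to_first(key, !duplicated(key))
  nodes <- allnodes[!duplicated(ids), , drop = FALSE]
  tri <- matrix(ids[alltri], ncol = 3)
  # drop degenerate triangles (can appear if a block edge collapses)
  keep_t <- abs(tri_signed_areas(nodes, tri)) > 1e-12 * scale^2
  tri <- tri[keep_t, , drop = FALSE]
  # --- tag boundary edges geometrically ---
  be <- boundary_edges_of(tri)
  mid <- (nodes[be[, 1], , drop = FALSE] + nodes[be[, 2], , drop = FALSE]) / 2
  tol <- 1e-6 * scale
  tag <- rep("wall", nrow(be))
  tag[abs(mid[, 1] - x_in) < tol] <- "inlet"
  along1 <- (mid[, 1] - end1c[1]) * d1[1] + (mid[, 2] - end1c[2]) * d1[2]
  along2 <- (mid[, 1] - end2c[1]) * d2[1] + (mid[, 2] - end2c[2]) * d2[2]
  tag[abs(along1) < tol] <- "outlet1"
  tag[abs(along2) < tol] <- "outlet2"
  bedf <- data.frame(n1 = be[, 1], n2 = be[, 2], tag = tag,
                     stringsAsFactors = FALSE)
  em <- eulerian_mesh(nodes * 1e-4, tri, bedf)  # micrometres -> cm
  attr(em, "apex_x") <- M0[1] * 1e-4
  attr(em, "geom") <- g
  attr(em, "outlet_dirs") <- list(outlet1 = d1, outlet2 = d2,
                                  w1 = g$w1 * 1e-4, w2 = g$w2 * 1e-4,
                                  end1 = end1c * 1e-4, end2 = end2c * 1e-4,
                                  n1v = n1v, n2v = n2v)
  em
}

# --- two-layer fold -------------------------------------------------------

#' Two-layer fold (vocal-fold-like) solid meshes
#'
#' Builds a mirrored pair of trapezoidal two-layer elastic bodies attached to
#' the channel walls: a lower fold on the bottom wall and its exact mirror
#' image about the channel centerline.  Each element carries a layer label,
#' `"cover"` for the outer (surface) layer and `"body"` for the interior.
#'
#' @param base_x0 streamwise position of the upstream base corner (cm).
#' @param length streamwise extent of the fold base (cm).
#' @param height fold height, i.e. protrusion into the channel (cm).
#' @param taper fraction of `length` by which each top corner is inset.
#' @param cover_frac thickness fraction of the cover layer (of `height`),
#'   in (0, 1); `body` takes the rest.
#' @param channel_height full channel height (cm); the centerline sits at
#'   `y0 + channel_height / 2`.
#' @param y0 bottom wall height (cm).
#' @param h target element size (cm).
#' @return list with components `down` and `up` ([lagrangian_mesh()]s); each
#'   carries attribute `fixed_nodes` (wall-attached node indices).
#' @export
generate_two_layer_fold_mesh <- function(base_x0 = 0.3, length = 0.35,
                                         height = 0.45, taper = 0.3,
                                         cover_frac = 0.3,
                                         channel_height = 1.0, y0 = 0,
                                         h = 0.05) {
  if (cover_frac <= 0 || cover_frac >= 1)
    stop("configuration error: cover_frac must be in (0, 1)")
  body_frac <- 1 - cover_frac
  if (cover_frac + body_frac > 1 + 1e-12)
    stop("configuration error: layer fractions sum above 1")
  if (length <= 0 || height <= 0 || taper < 0 || taper >= 0.5)
    stop("configuration error: invalid fold dimensions")
  if (2 * height >= channel_height)
    stop("configuration error: folds thicker than the channel")
  ns <- max(4L, as.integer(round(length / h)))
  nt <- max(3L, as.integer(round(height / h)))
  xi <- seq(0, 1, length.out = ns + 1L)
  eta <- seq(0, 1, length.out = nt + 1L)
  xb <- base_x0 + xi * length
  xt <- base_x0 + taper * length + xi * (1 - 2 * taper) * length
  nodes <- matrix(0, (ns + 1L) * (nt + 1L), 2L)
  idx <- matrix(seq_len((ns + 1L) * (nt + 1L)), ns + 1L, nt + 1L)
  for (j in seq_len(nt + 1L)) {
    e <- eta[j]
    nodes[idx[, j], 1] <- (1 - e) * xb + e * xt
    nodes[idx[, j], 2] <- y0 + e * height
  }
  tri <- grid_triangles(idx)
  # element layer label by mean eta
  jmid <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  layer <- ifelse((jmid - y0) / height > body_frac, "cover", "body")
  lm_down <- lagrangian_mesh(nodes, tri, layer = layer)
  attr(lm_down, "fixed_nodes") <- as.integer(idx[, 1L])
  # mirror about the centerline
  yc <- y0 + channel_height / 2
  nodes_up <- cbind(nodes[, 1], 2 * yc - nodes[, 2])
  lm_up <- lagrangian_mesh(nodes_up, tri, layer = layer)
  attr(lm_up, "fixed_nodes") <- as.integer(idx[, 1L])
  list(down = lm_down, up = lm_up)
}
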
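#' @importFrom Matrix sparseMatrix Diagonal
#' @importFrom stats fft runif
#' @importFrom utils head tail read.table write.csv read.csv
NULL

# Internal unit is cm (CGS) for both meshes; configuration-level helpers
# convert micrometres at the boundary (um * 1e-4 -> cm).
um <- function(x) x * 1e-4

#' Eulerian (fluid) mesh
#'
#' A fixed unstructured triangulation of the computational domain.  Node
#' coordinates are in cm.  Triangles are stored with positive (counter-
#' clockwise) orientation; constructors reorder inverted triangles.
#'
#' @param nodes numeric matrix, n x 2, node coordinates (cm).
#' @param triangles integer matrix, m x 3, 1-based node indices.
#' @param boundary_edges data.frame with columns `n1`, `n2`, `tag`; every
#'   boundary edge of the triangulation must appear with some tag
#'   (use `"untagged"` for edges without a physical group).
#' @return object of class `eulerian_mesh` with fields `nodes`, `tri`,
#'   `boundary_edges` and `tags` (named list of boundary node index sets).
#' @export
eulerian_mesh <- function(nodes, triangles, boundary_edges = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  stopifnot(ncol(nodes) == 2)
  tri <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (any(tri < 1L) || any(tri > nrow(nodes)))
    stop("triangle indices out of range")
  a <- tri_signed_areas(nodes, tri)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  if (any(abs(tri_signed_areas(nodes, tri)) < 1e-300))
    stop("degenerate (zero-area) triangle in mesh")
  check_no_duplicate_nodes(nodes)
  if (is.null(boundary_edges)) {
    be <- boundary_edges_of(tri)
    boundary_edges <- data.frame(n1 = be[, 1], n2 = be[, 2],
                                 tag = "untagged",
                                 stringsAsFactors = FALSE)
  }
  tags <- split(c(boundary_edges$n1, boundary_edges$n2),
                rep(boundary_edges$tag, 2L))
  tags <- lapply(tags, function(ix) sort(unique(as.integer(ix))))
  m <- structure(list(nodes = nodes, tri = tri,
                      boundary_edges = boundary_edges, tags = tags),
                 class = "eulerian_mesh")
  m
}

#' Lagrangian (solid) mesh
#'
#' A moving triangulation attached to solid material points.  `ref` holds the
#' reference coordinates X^s, `cur` the current coordinates x^s (equal at
#' t = 0).  `boundary` is the ordered closed loop of boundary node indices
#' (counter-clockwise, so that segment normals point outward).
#'
#' @param ref numeric matrix, n x 2, reference coordinates (cm).
#' @param triangles integer matrix, m x 3.
#' @param boundary integer vector, ordered boundary loop (not repeated at
#'   the end).  If `NULL` it is extracted from the triangulation.
#' @param layer optional character vector, one label per element.
#' @export
lagrangian_mesh <- function(ref, triangles, boundary = NULL, layer = NULL) {
  ref <- as.matrix(ref)
  storage.mode(ref) <- "double"
  tri <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  a <- tri_signed_areas(ref, tri)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  check_no_duplicate_nodes(ref)
  if (is.null(boundary)) {
    loops <- boundary_loops_of(tri)
  } else if (is.list(boundary)) {
    loops <- lapply(boundary, as.integer)
  } else {
    loops <- list(as.integer(boundary))
  }
  # orient loops counter-clockwise so edge normals (dy, -dx) point outward
  loops <- lapply(loops, function(lp) {
    if (polygon_area(ref[lp, , drop = FALSE]) < 0) rev(lp) else lp
  })
  if (!is.null(layer)) {
    layer <- as.character(layer)
    stopifnot(length(layer) == nrow(tri))
  }
  structure(list(ref = ref, cur = ref, tri = tri, boundary = loops[[1L]],
                 loops = loops, layer = layer),
            class = "lagrangian_mesh")
}

#' @export
print.eulerian_mesh <- function(x, ...) {
  cat(sprintf("<eulerian_mesh> %d nodes, %d triangles, tags: %s\n",
              nrow(x$nodes), nrow(x$tri),
              paste(names(x$tags), collapse = ", ")))
  invisible(x)
}

#' @export
print.lagrangian_mesh <- function(x, ...) {
  cat(sprintf("<lagrangian_mesh> %d nodes, %d triangles, %d boundary nodes\n",
              nrow(x$ref), nrow(x$tri), length(x$boundary)))
  invisible(x)
}

check_no_duplicate_nodes <- function(nodes, tol = 1e-12) {
  scale <- max(1, max(abs(nodes)))
  key <- paste(round(nodes[, 1] / (tol * scale)),
               round(nodes[, 2] / (tol * scale)))
  if (anyDuplicated(key))
    stop("duplicate nodes within tolerance")
  invisible(TRUE)
}

tri_signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Signed area of a polygon (shoelace formula)
#' @param p matrix of vertex coordinates, ordered along the loop.
#' @export
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

# all edges that belong to exactly one triangle, as a 2-column matrix
boundary_edges_of <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

# chain the boundary edges of a triangulation into one or more closed loops
# (a mesh may hold several disconnected bodies, e.g. a mirrored fold pair)
boundary_loops_of <- function(tri) {
  be <- boundary_edges_of(tri)
  if (nrow(be) == 0L) stop("mesh has no boundary")
  used <- rep(FALSE, nrow(be))
  loops <- list()
  while (any(!used)) {
    k0 <- which(!used)[1]
    loop <- be[k0, 1]
    cur <- be[k0, 2]
    used[k0] <- TRUE
    while (cur != loop[1]) {
      loop <- c(loop, cur)
      j <- which(!used & be[, 1] == cur)[1]
      if (is.na(j)) stop("boundary is not a union of closed loops")
      cur <- be[j, 2]
      used[j] <- TRUE
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Outward unit normals of the solid boundary
#'
#' One normal per boundary segment (from node i to node i+1 of each loop),
#' evaluated on the current configuration.  All loops of a multi-body mesh
#' are concatenated.
#' @param lm a `lagrangian_mesh`.
#' @return list with `mid` (segment midpoints), `normal` (unit outward
#'   normals), `len` (segment lengths), `n1`, `n2` (segment node indices) —
#'   one row per segment.
#' @export
boundary_normals <- function(lm) {
  loops <- lm$loops %||% list(lm$boundary)
  mid <- normal <- matrix(0, 0L, 2L)
  len <- numeric(0)
  n1 <- n2 <- integer(0)
  for (loop in loops) {
    p <- lm$cur[loop, , drop = FALSE]
    n <- nrow(p)
    j <- c(2:n, 1)
    d <- p[j, , drop = FALSE] - p
    l <- sqrt(rowSums(d^2))
    # loop is CCW: outward normal of edge (dx,dy) is (dy,-dx)/len
    normal <- rbind(normal, cbind(d[, 2], -d[, 1]) / l)
    mid <- rbind(mid, (p + p[j, , drop = FALSE]) / 2)
    len <- c(len, l)
    n1 <- c(n1, loop); n2 <- c(n2, loop[j])
  }
  list(mid = mid, normal = normal, len = len, n1 = n1, n2 = n2)
}

# --- point location -------------------------------------------------------

# spatial hash over the (fixed) fluid mesh: triangle bounding boxes binned
# on a uniform grid; built once per mesh and cached in the mesh object.
build_point_locator <- function(em) {
  nodes <- em$nodes; tri <- em$tri
  nb <- max(4L, as.integer(ceiling(sqrt(nrow(tri)))))
  xr <- range(nodes[, 1]); yr <- range(nodes[, 2])
  dx <- max(diff(xr), 1e-300) / nb
  dy <- max(diff(yr), 1e-300) / nb
  tx1 <- pmin(nodes[tri[, 1], 1], nodes[tri[, 2], 1], nodes[tri[, 3], 1])
  tx2 <- pmax(nodes[tri[, 1], 1], nodes[tri[, 2], 1], nodes[tri[, 3], 1])
  ty1 <- pmin(nodes[tri[, 1], 2], nodes[tri[, 2], 2], nodes[tri[, 3], 2])
  ty2 <- pmax(nodes[tri[, 1], 2], nodes[tri[, 2], 2], nodes[tri[, 3], 2])
  ix1 <- pmax(1L, pmin(nb, 1L + floor((tx1 - xr[1]) / dx)))
  ix2 <- pmax(1L, pmin(nb, 1L + floor((tx2 - xr[1]) / dx)))
  iy1 <- pmax(1L, pmin(nb, 1L + floor((ty1 - yr[1]) / dy)))
  iy2 <- pmax(1L, pmin(nb, 1L + floor((ty2 - yr[1]) / dy)))
  bins <- vector("list", nb * nb)
  for (t in seq_len(nrow(tri))) {
    for (ix in ix1[t]:ix2[t]) for (iy in iy1[t]:iy2[t]) {
      b <- (iy - 1L) * nb + ix
      bins[[b]] <- c(bins[[b]], t)
    }
  }
  list(nb = nb, xr = xr, yr = yr, dx = dx, dy = dy, bins = bins)
}

get_locator <- function(em) {
  loc <- attr(em, "locator")
  if (is.null(loc)) loc <- build_point_locator(em)
  loc
}

#' Attach a cached spatial hash to a mesh
#'
#' The Eulerian mesh never moves, so its point-location hash can be built
#' once.  Returns the mesh with the locator stored as an attribute; all
#' point-location calls reuse it.
#' @param em an `eulerian_mesh`.
#' @export
with_locator <- function(em) {
  attr(em, "locator") <- build_point_locator(em)
  em
}

bary_coords <- function(nodes, tri, elem, pts) {
  a <- nodes[tri[elem, 1], , drop = FALSE]
  b <- nodes[tri[elem, 2], , drop = FALSE]
  c_ <- nodes[tri[elem, 3], , drop = FALSE]
  det <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
         (c_[, 1] - a[, 1]) * (b[, 2] - a[, 2])
  l2 <- ((pts[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
         (c_[, 1] - a[, 1]) * (pts[, 2] - a[, 2])) / det
  l3 <- ((b[, 1] - a[, 1]) * (pts[, 2] - a[, 2]) -
         (pts[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / det
  cbind(1 - l2 - l3, l2, l3)
}

#' Locate points in the fluid mesh
#'
#' Finds, for every query point, the host triangle and the barycentric
#' coordinates within it, using a cell-bin spatial hash.  A point that falls
#' outside the mesh raises an immersion-violation error: the solid must
#' remain immersed in the fluid domain at all times.
#'
#' @param em an `eulerian_mesh` (optionally carrying a cached locator,
#'   see [with_locator()]).
#' @param pts numeric matrix, k x 2.
#' @param tol geometric tolerance on the barycentric coordinates.
#' @param on_outside `"error"` raises an immersion violation for points
#'   outside the mesh, `"na"` marks them with `elem = NA` instead.
#' @return list with `elem` (integer k) and `bary` (k x 3 matrix, rows
#'   non-negative and summing to one).
#' @export
locate_points <- function(em, pts, tol = 1e-10,
                          on_outside = c("error", "na")) {
  on_outside <- match.arg(on_outside)
  pts <- matrix(as.numeric(pts), ncol = 2)
  loc <- get_locator(em)
  k <- nrow(pts)
  elem <- integer(k)
  bary <- matrix(0, k, 3)
  ix <- pmax(1L, pmin(loc$nb, 1L + floor((pts[, 1] - loc$xr[1]) / loc$dx)))
  iy <- pmax(1L, pmin(loc$nb, 1L + floor((pts[, 2] - loc$yr[1]) / loc$dy)))
  bin <- (iy - 1L) * loc$nb + ix
  for (i in seq_len(k)) {
    cand <- loc$bins[[bin[i]]]
    found <- FALSE
    if (!is.null(cand)) {
      bc <- bary_coords(em$nodes, em$tri, cand,
                        pts[rep(i, length(cand)), , drop = FALSE])
      ok <- which(bc[, 1] >= -tol & bc[, 2] >= -tol & bc[, 3] >= -tol)
      if (length(ok)) {
        j <- ok[1]
        elem[i] <- cand[j]
        bary[i, ] <- pmin(pmax(bc[j, ], 0), 1)
        bary[i, ] <- bary[i, ] / sum(bary[i, ])
        found <- TRUE
      }
    }
    if (!found) {
      if (on_outside == "error")
        stop(sprintf(
          "immersion violation: point (%g, %g) is outside the fluid domain",
          pts[i, 1], pts[i, 2]))
      elem[i] <- NA_integer_
    }
  }
  list(elem = elem, bary = bary)
}

# Pull points that stepped through a wall back to the last interior position
# along their displacement segment (bisection); a no-slip wall is
# impenetrable, so this only corrects the overshoot of a single advection
# step.  Returns the corrected points and which ones were clamped.
clamp_into_domain <- function(em, old_pts, new_pts, iters = 25L) {
  loc <- locate_points(em, new_pts, on_outside = "na")
  out <- which(is.na(loc$elem))
  for (i in out) {
    lo <- 0; hi <- 1
    for (k in seq_len(iters)) {
      mid <- (lo + hi) / 2
      p <- old_pts[i, ] + mid * (new_pts[i, ] - old_pts[i, ])
      ok <- !is.na(locate_points(em, matrix(p, 1, 2),
                                 on_outside = "na")$elem[1])
      if (ok) lo <- mid else hi <- mid
    }
    new_pts[i, ] <- old_pts[i, ] + 0.98 * lo * (new_pts[i, ] - old_pts[i, ])
  }
  list(pts = new_pts, clamped = out)
}

# --- shared P1 element data ----------------------------------------------

# Constant shape-function gradients and areas for linear triangles.
# Returns area (m), dNx, dNy (m x 3): gradient of shape function of local
# node j in element e.
fem_element_data <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)  # 2*area
  dNx <- cbind(y2 - y3, y3 - y1, y1 - y2) / a2
  dNy <- cbind(x3 - x2, x1 - x3, x2 - x1) / a2
  list(area = a2 / 2, dNx = dNx, dNy = dNy)
}

# lumped nodal areas (row sums of the lumped mass matrix, unit density)
lumped_areas <- function(nodes, tri) {
  ed <- fem_element_data(nodes, tri)
  v <- rep(ed$area / 3, 3L)
  as.numeric(unname(tapply(v, factor(as.vector(tri),
                                     levels = seq_len(nrow(nodes))), sum,
                           default = 0)))
}

# typical element length scale (sqrt of mean element area * 2)
mesh_h <- function(nodes, tri) {
  sqrt(2 * mean(abs(tri_signed_areas(nodes, tri))))
}
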
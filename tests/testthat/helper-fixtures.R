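# Shared fixtures and independent oracles, all built in code.

# small box mesh with a cached locator/femdata
box_mesh <- function(L = 2, H = 1, h = 0.1)
  with_femdata(generate_channel_mesh(L, H, h))

# brute-force point location: scan every triangle (oracle for locate_points)
brute_locate <- function(em, pts, tol = 1e-10) {
  k <- nrow(pts)
  elem <- integer(k)
  for (i in seq_len(k)) {
    found <- FALSE
    for (t in seq_len(nrow(em$tri))) {
      a <- em$nodes[em$tri[t, 1], ]; b <- em$nodes[em$tri[t, 2], ]
      cc <- em$nodes[em$tri[t, 3], ]
      det <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
      l2 <- ((pts[i, 1] - a[1]) * (cc[2] - a[2]) -
               (cc[1] - a[1]) * (pts[i, 2] - a[2])) / det
      l3 <- ((b[1] - a[1]) * (pts[i, 2] - a[2]) -
               (pts[i, 1] - a[1]) * (b[2] - a[2])) / det
      l1 <- 1 - l2 - l3
      if (l1 >= -tol && l2 >= -tol && l3 >= -tol) {
        elem[i] <- t; found <- TRUE; break
      }
    }
    if (!found) elem[i] <- NA_integer_
  }
  elem
}

# random points strictly inside a channel mesh
random_interior_points <- function(n, L = 2, H = 1, margin = 0.05) {
  cbind(runif(n, margin, L - margin), runif(n, margin, H - margin))
}

# full 3D isotropic Hooke stiffness from inverting the compliance matrix
# (independent oracle for the plane-strain elasticity matrix)
hooke3d_stress <- function(E, nu, eps6) {
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- -nu / E
  diag(S)[1:3] <- 1 / E
  diag(S)[4:6] <- 2 * (1 + nu) / E
  C <- solve(S)
  as.numeric(C %*% eps6)
}

# densely resampled minimum distance between a polygon boundary and a line
# y = y0 (oracle for glottis_width)
resampled_min_dist <- function(poly, y0, n_per_seg = 200) {
  np <- nrow(poly)
  j <- c(2:np, 1)
  d <- Inf
  for (i in seq_len(np)) {
    t <- seq(0, 1, length.out = n_per_seg)
    y <- poly[i, 2] + t * (poly[j[i], 2] - poly[i, 2])
    d <- min(d, min(abs(y - y0)))
  }
  d
}
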
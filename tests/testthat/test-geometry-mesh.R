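# Mesh generators, invariants, point location, I/O round trips.

test_that("channel mesh matches the structured template and tags all edges", {
  em <- generate_channel_mesh(4, 1, 0.1)
  nx <- round(4 / 0.1); ny <- round(1 / 0.1)
  expect_equal(nrow(em$nodes), (nx + 1) * (ny + 1))
  expect_equal(nrow(em$tri), 2 * nx * ny)
  expect_equal(sum(tri_signed_areas(em$nodes, em$tri)), 4, tolerance = 1e-12)
  # every boundary edge of the triangulation carries a tag
  expect_setequal(unique(em$boundary_edges$tag), c("inlet", "outlet", "wall"))
  expect_equal(nrow(em$boundary_edges), 2 * nx + 2 * ny)
  expect_error(generate_channel_mesh(4, 0, 0.1), "configuration error")
  expect_error(generate_channel_mesh(-1, 1, 0.1), "configuration error")
})

test_that("disc mesh area converges to pi r^2 and matches the shoelace oracle", {
  lm <- generate_disc_mesh(c(0, 0), 2.66e-4, 2.66e-4 / 8)
  area <- sum(tri_signed_areas(lm$ref, lm$tri))
  expect_lt(abs(area - pi * (2.66e-4)^2) / (pi * (2.66e-4)^2), 0.02)
  # triangulated area equals the boundary-polygon area exactly
  lm1 <- generate_disc_mesh(c(0, 0), 1, 1 / 16)
  expect_equal(sum(tri_signed_areas(lm1$ref, lm1$tri)),
               polygon_area(lm1$ref[lm1$boundary, ]), tolerance = 1e-12)
  # boundary normals point radially outward for a convex body
  bn <- boundary_normals(lm1)
  expect_true(all(rowSums(bn$normal * bn$mid) > 0))
  expect_error(generate_disc_mesh(c(0, 0), 1, 2), "configuration error")
})

test_that("bifurcation mesh honours the diameter ratio and symmetry", {
  g <- bifurcation_geometry(w0 = 8, r_d = 1.44)
  expect_equal(g$w1 / g$w2, 1.44, tolerance = 1e-12)
  em <- generate_bifurcation_mesh(g)
  expect_setequal(names(em$tags), c("inlet", "outlet1", "outlet2", "wall"))
  # mesh covers its outline exactly (no overlapping blocks)
  loops <- ifem2d:::boundary_loops_of(em$tri)
  expect_length(loops, 1L)
  expect_equal(sum(tri_signed_areas(em$nodes, em$tri)),
               abs(polygon_area(em$nodes[loops[[1]], ])), tolerance = 1e-9)
  # symmetric parameters give a mirror-symmetric mesh (nodes map onto nodes)
  gs <- bifurcation_geometry(w0 = 8, r_d = 1)
  ems <- generate_bifurcation_mesh(gs)
  n <- ems$nodes
  h_cm <- gs$h * 1e-4
  d <- vapply(seq_len(nrow(n)), function(i)
    min(sqrt((n[, 1] - n[i, 1])^2 + (n[, 2] + n[i, 2])^2)), 0)
  expect_lt(max(d), h_cm)
  expect_error(bifurcation_geometry(mother_len = 0), "configuration error")
  expect_error(bifurcation_geometry(beta1 = 0), "configuration error")
})

test_that("two-layer fold meshes partition into layers and mirror exactly", {
  f <- generate_two_layer_fold_mesh()
  expect_setequal(unique(f$down$layer), c("cover", "body"))
  expect_equal(length(f$down$layer), nrow(f$down$tri))
  # mirroring the upper fold about the centerline reproduces the lower fold
  yc <- 0.5
  refl <- cbind(f$up$ref[, 1], 2 * yc - f$up$ref[, 2])
  expect_equal(refl, f$down$ref, tolerance = 1e-14)
  expect_identical(f$up$layer, f$down$layer)
  expect_error(generate_two_layer_fold_mesh(cover_frac = 0),
               "configuration error")
  expect_error(generate_two_layer_fold_mesh(length = -1),
               "configuration error")
})

test_that("locate_points agrees with the brute-force scan and flags outsiders", {
  set.seed(42)
  em <- box_mesh()
  pts <- random_interior_points(100)
  loc <- locate_points(em, pts)
  expect_true(all(loc$bary >= 0 & loc$bary <= 1))
  expect_equal(rowSums(loc$bary), rep(1, 100), tolerance = 1e-12)
  # reconstructed positions match the query points
  rec <- matrix(0, 100, 2)
  for (a in 1:3)
    rec <- rec + loc$bary[, a] * em$nodes[em$tri[cbind(loc$elem, a)], ]
  expect_equal(rec, pts, tolerance = 1e-12)
  # host elements agree with the exhaustive scan wherever the point is
  # strictly interior to its host (ties on edges may differ)
  bf <- brute_locate(em, pts)
  strict <- apply(loc$bary, 1, min) > 1e-8
  expect_true(mean(loc$elem[strict] == bf[strict]) > 0.99)
  # element centroid -> equal barycentric weights; mesh node -> Kronecker
  cen <- (em$nodes[em$tri[7, 1], ] + em$nodes[em$tri[7, 2], ] +
            em$nodes[em$tri[7, 3], ]) / 3
  lc <- locate_points(em, matrix(cen, 1))
  expect_equal(as.numeric(lc$bary), rep(1 / 3, 3), tolerance = 1e-12)
  ln <- locate_points(em, em$nodes[15, , drop = FALSE])
  expect_equal(sort(as.numeric(ln$bary)), c(0, 0, 1), tolerance = 1e-12)
  expect_error(locate_points(em, matrix(c(10, 10), 1)),
               "immersion violation")
})

test_that("gmsh round trip preserves coordinates and connectivity bit-exactly", {
  em <- generate_channel_mesh(1, 0.5, 0.25)
  path <- tempfile(fileext = ".msh")
  write_mesh(em, path)
  em2 <- read_mesh(path)
  expect_identical(em$nodes, em2$nodes)
  expect_identical(em$tri, em2$tri)
  expect_setequal(names(em2$tags), names(em$tags))
  lm <- generate_disc_mesh(c(0.5, 0.25), 0.2, 0.07)
  path2 <- tempfile(fileext = ".msh")
  write_mesh(lm, path2)
  lm2 <- read_mesh(path2, lagrangian = TRUE)
  expect_identical(lm$ref, lm2$ref)
  expect_identical(lm$tri, lm2$tri)
})

test_that("VTU state output writes well-formed XML with the expected fields", {
  em <- box_mesh(1, 1, 0.25)
  lm <- generate_disc_mesh(c(0.5, 0.5), 0.2, 0.07)
  props <- fluid_properties(1, 1)
  mat <- material_model("linear-elastic", E = 10, nu = 0.3, rho = 1)
  sim <- ifem_sim(em, lm, props, mat, dt = 0.01,
                  fluid_bcs = list(list(tag = "wall", type = "noslip"),
                                   list(tag = "inlet", type = "noslip"),
                                   list(tag = "outlet", type = "noslip")))
  dir <- tempfile()
  paths <- write_state(dir, 1L, sim)
  expect_true(all(file.exists(paths)))
  doc <- xml2::read_xml(paths[1])
  expect_equal(xml2::xml_name(doc), "VTKFile")
  arrays <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  expect_true("velocity" %in% xml2::xml_attr(arrays, "Name"))
  expect_true("pressure" %in% xml2::xml_attr(arrays, "Name"))
})
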
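# Solid mechanics: strain, constitutive laws, internal forces, statics and
# Newmark dynamics.

bar_mesh <- function(L = 1, H = 0.25, h = 0.05) {
  ch <- generate_channel_mesh(L, H, h)
  lagrangian_mesh(ch$nodes, ch$tri)
}

test_that("strain vanishes for rigid motions and matches closed forms", {
  lm <- bar_mesh()
  n <- nrow(lm$ref)
  expect_equal(max(abs(compute_strain(lm, matrix(0.3, n, 2)))), 0,
               tolerance = 1e-14)
  # u = (a x, 0) -> exx = a
  a <- 0.01
  eps <- compute_strain(lm, cbind(a * lm$ref[, 1], 0))
  expect_equal(eps[, "exx"], rep(a, nrow(lm$tri)), tolerance = 1e-12)
  expect_equal(max(abs(eps[, c("eyy", "exy")])), 0, tolerance = 1e-13)
  # infinitesimal rotation u = theta (-y, x) -> eps = 0
  th <- 1e-3
  eps2 <- compute_strain(lm, th * cbind(-lm$ref[, 2], lm$ref[, 1]))
  expect_equal(max(abs(eps2)), 0, tolerance = 1e-14)
})

test_that("plane-strain Hooke law matches the 3D compliance-inversion oracle", {
  mat <- material_model("linear-elastic", E = 1e5, nu = 0.3, rho = 1)
  eps <- matrix(c(0.01, 0, 0), 1)
  sig <- constitutive_stress(mat, eps)
  oracle <- hooke3d_stress(1e5, 0.3, c(0.01, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(sig[1, "sxx"]), oracle[1], tolerance = 1e-12)
  expect_equal(as.numeric(sig[1, "sxx"]),
               1e5 * (1 - 0.3) / ((1 + 0.3) * (1 - 0.6)) * 0.01,
               tolerance = 1e-12)
  expect_equal(as.numeric(sig[1, "syy"]), oracle[2], tolerance = 1e-12)
  # zero state, zero rate -> zero stress
  expect_equal(max(abs(constitutive_stress(mat, matrix(0, 1, 3),
                                           matrix(0, 1, 3)))), 0)
  # pure rate loading: sigma = eta * strain rate (componentwise)
  matv <- material_model("viscoelastic", E = 1e5, nu = 0.3, rho = 1, eta = 7)
  sigv <- constitutive_stress(matv, matrix(0, 1, 3), matrix(c(3, 0, 2), 1))
  expect_equal(as.numeric(sigv[1, "sxx"]), 7 * 3, tolerance = 1e-12)
  expect_equal(as.numeric(sigv[1, "sxy"]), 7 * 2, tolerance = 1e-12)
  expect_error(constitutive_stress(material_model("mooney-rivlin", E = 1,
                                                  nu = 0.3, rho = 1),
                                   eps), "deformation gradient")
})

test_that("internal forces are momentum-free and match hand-integrated P1 forms", {
  lm <- bar_mesh()
  m <- nrow(lm$tri)
  expect_equal(max(abs(internal_force(lm, matrix(0, m, 3)))), 0)
  # single unit right triangle, uniform stress: closed-form edge resultants
  tr <- lagrangian_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1))
  sig <- matrix(c(5, -2, 3), 1)  # sxx, syy, sxy
  f <- internal_force(tr, sig)
  expect_equal(unname(f[1, ]), c((5 + 3) / 2, (3 - 2) / 2), tolerance = 1e-14)
  expect_equal(unname(f[2, ]), c(-5 / 2, -3 / 2), tolerance = 1e-14)
  expect_equal(unname(f[3, ]), c(-3 / 2, 2 / 2), tolerance = 1e-14)
  expect_equal(unname(colSums(f)), c(0, 0), tolerance = 1e-14)
  # random stress state: forces sum to zero (no boundary traction)
  set.seed(3)
  sigr <- matrix(rnorm(3 * m), m, 3)
  fr <- internal_force(lm, sigr)
  expect_equal(unname(colSums(fr)), c(0, 0), tolerance = 1e-12 * max(abs(fr)))
})

test_that("internal force is minus the strain-energy gradient", {
  set.seed(5)
  lm <- bar_mesh(1, 0.5, 0.25)
  n <- nrow(lm$ref)
  mat <- material_model("linear-elastic", E = 100, nu = 0.3, rho = 1)
  u <- matrix(rnorm(2 * n, sd = 1e-3), n, 2)
  energy <- function(uv) {
    um <- matrix(uv, n, 2)
    eps <- compute_strain(lm, um)
    sig <- constitutive_stress(mat, eps)
    A <- abs(tri_signed_areas(lm$ref, lm$tri))
    sum(A * 0.5 * (eps[, 1] * sig[, 1] + eps[, 2] * sig[, 2] +
                     2 * eps[, 3] * sig[, 3]))
  }
  f <- internal_force(lm, constitutive_stress(mat, compute_strain(lm, u)))
  h <- 1e-7
  idx <- sample(2 * n, 12)
  for (i in idx) {
    up <- as.numeric(u); um <- as.numeric(u)
    up[i] <- up[i] + h; um[i] <- um[i] - h
    gfd <- (energy(up) - energy(um)) / (2 * h)
    expect_equal(as.numeric(f)[i], -gfd, tolerance = 1e-5 * max(1, abs(gfd)))
  }
})

test_that("static patch test is exact: uniform traction gives uniform stress", {
  lm <- bar_mesh(1, 0.5, 0.1)
  mat <- material_model("linear-elastic", E = 1e5, nu = 0.3, rho = 1)
  left <- which(abs(lm$ref[, 1]) < 1e-12)
  corner <- which(abs(lm$ref[, 1]) < 1e-12 & abs(lm$ref[, 2]) < 1e-12)
  right_edges <- cbind(which(abs(lm$ref[, 1] - 1) < 1e-12 &
                               lm$ref[, 2] < 0.5 - 1e-12),
                       which(abs(lm$ref[, 1] - 1) < 1e-12 &
                               lm$ref[, 2] > 1e-12))
  bcs <- list(dirichlet = list(list(nodes = left, comp = 1L),
                               list(nodes = corner, comp = 2L)),
              traction = list(list(edges = right_edges, value = c(100, 0))))
  st <- solve_solid_static(lm, mat, bcs)
  sig <- constitutive_stress(mat, compute_strain(lm, st$u))
  expect_equal(sig[, "sxx"], rep(100, nrow(lm$tri)), tolerance = 1e-10)
  expect_equal(max(abs(sig[, "syy"])), 0, tolerance = 1e-9)
  expect_equal(max(abs(sig[, "sxy"])), 0, tolerance = 1e-9)
})

test_that("Newmark dynamics: rest stays at rest; positions update linearly", {
  lm <- bar_mesh(1, 0.25, 0.125)
  mat <- material_model("linear-elastic", E = 1e4, nu = 0.3, rho = 1)
  st <- solid_state(lm)
  left <- which(abs(lm$ref[, 1]) < 1e-12)
  out <- solve_solid_dynamics(lm, st, mat,
                              list(dirichlet = list(list(nodes = left))),
                              dt = 1e-3)
  expect_equal(max(abs(out$u)), 0, tolerance = 1e-14)
  expect_equal(max(abs(out$v)), 0, tolerance = 1e-12)
  # update_positions: v = 0 unchanged; uniform v shifts; two halves = one full
  st$v <- matrix(rep(c(1, 0), each = nrow(lm$ref)), ncol = 2)
  s1 <- update_positions(st, 0.1)
  expect_equal(s1$u[, 1], rep(0.1, nrow(lm$ref)))
  s2 <- update_positions(update_positions(st, 0.05), 0.05)
  expect_equal(s2$u, s1$u, tolerance = 1e-15)
})

test_that("cantilever-bar fundamental frequency matches the closed form", {
  # axial mode of a fixed-free bar: f1 = sqrt(E/rho) / (4 L); nu = 0 keeps
  # the plane-strain modulus equal to E
  L <- 1
  lm <- bar_mesh(L, 0.125, 1 / 32)
  mat <- material_model("linear-elastic", E = 1e5, nu = 0, rho = 1)
  f_exact <- sqrt(1e5 / 1) / (4 * L)
  dt <- 1 / (f_exact * 200)
  st <- solid_state(lm)
  st$u[, 1] <- 1e-4 * sin(pi * lm$ref[, 1] / (2 * L))
  left <- which(abs(lm$ref[, 1]) < 1e-12)
  bcs <- list(dirichlet = list(list(nodes = left)))
  tip <- which.max(lm$ref[, 1] + lm$ref[, 2] * 1e-3)
  series <- numeric(400)
  for (k in seq_len(400)) {
    st <- solve_solid_dynamics(lm, st, mat, bcs, dt)
    series[k] <- st$u[tip, 1]
  }
  zc <- which(diff(sign(series)) != 0)
  f_meas <- 1 / (2 * mean(diff(zc)) * dt)
  expect_equal(f_meas, f_exact, tolerance = 0.05)
})

test_that("undamped free vibration conserves energy over 100 steps", {
  lm <- bar_mesh(1, 0.25, 0.125)
  mat <- material_model("linear-elastic", E = 1e4, nu = 0.3, rho = 1)
  st <- solid_state(lm)
  st$u[, 1] <- 1e-3 * lm$ref[, 1]
  left <- which(abs(lm$ref[, 1]) < 1e-12)
  bcs <- list(dirichlet = list(list(nodes = left)))
  mlump <- mat$rho * ifem2d:::lumped_areas(lm$ref, lm$tri)
  total_energy <- function(s) {
    eps <- compute_strain(lm, s$u)
    sig <- constitutive_stress(mat, eps)
    A <- abs(tri_signed_areas(lm$ref, lm$tri))
    el <- sum(A * 0.5 * (eps[, 1] * sig[, 1] + eps[, 2] * sig[, 2] +
                           2 * eps[, 3] * sig[, 3]))
    el + 0.5 * sum(mlump * rowSums(s$v^2))
  }
  e0 <- total_energy(st)
  dt <- 2e-4
  for (k in 1:100) st <- solve_solid_dynamics(lm, st, mat, bcs, dt)
  expect_equal(total_energy(st), e0, tolerance = 0.02)
})

test_that("mooney-rivlin stress is consistent with linear elasticity at small strain", {
  matm <- material_model("mooney-rivlin", E = 1e4, nu = 0.3, rho = 1)
  matl <- material_model("linear-elastic", E = 1e4, nu = 0.3, rho = 1)
  lm <- bar_mesh(1, 0.5, 0.25)
  u <- cbind(1e-4 * lm$ref[, 1], -0.3e-4 * lm$ref[, 2])
  sig_m <- constitutive_stress(matm, NULL,
                               defgrad = ifem2d:::deformation_gradient(lm, u))
  sig_l <- constitutive_stress(matl, compute_strain(lm, u))
  # shear moduli agree to leading order; tolerance reflects the different
  # volumetric treatments of the two laws
  expect_equal(sig_m[, "sxy"], sig_l[, "sxy"], tolerance = 0.05)
  # rigid rotation produces no stress (objectivity of the finite-strain law)
  th <- 0.3
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  ur <- t(R %*% t(lm$ref)) - lm$ref
  sig_r <- constitutive_stress(matm, NULL,
                               defgrad = ifem2d:::deformation_gradient(lm, ur))
  expect_equal(max(abs(sig_r)), 0, tolerance = 1e-10)
})
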
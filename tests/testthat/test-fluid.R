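# Stabilized fluid solver: stress evaluation, analytic solutions,
# divergence diagnostics, variable density and pseudo-compressibility.

props_w <- fluid_properties(rho = 1, mu = 1)

test_that("effective density blends the indicator linearly and validates input", {
  I <- c(0, 0.25, 0.5, 1)
  expect_equal(effective_density(I, 1, 3), 1 + 2 * I)
  expect_equal(effective_density(I, 2, 2), rep(2, 4))
  expect_equal(effective_density(rep(0, 3), 1.5, 1000), rep(1.5, 3))
  expect_equal(effective_density(rep(1, 3), 1.5, 1000), rep(1000, 3))
  expect_error(effective_density(c(0.5, 1.2), 1, 2), "indicator invariant")
})

test_that("fluid stress reproduces closed forms for simple fields", {
  em <- box_mesh(1, 1, 0.25)
  n <- nrow(em$nodes)
  # static pressurized fluid: sigma = -p I
  st <- fluid_state(em, v = matrix(0, n, 2), p = rep(2, n))
  sig <- fluid_stress(em, st, props_w)
  expect_equal(sig[, "sxx"], rep(-2, nrow(em$tri)))
  expect_equal(sig[, "syy"], rep(-2, nrow(em$tri)))
  expect_equal(sig[, "sxy"], rep(0, nrow(em$tri)))
  # pure shear v = (y, 0): sxy = mu
  st2 <- fluid_state(em, v = cbind(em$nodes[, 2], 0))
  sig2 <- fluid_stress(em, st2, props_w)
  expect_equal(sig2[, "sxy"], rep(props_w$mu, nrow(em$tri)), tolerance = 1e-12)
  # rigid rotation v = (-y, x): deviatoric part vanishes
  st3 <- fluid_state(em, v = cbind(-em$nodes[, 2], em$nodes[, 1]))
  sig3 <- fluid_stress(em, st3, props_w)
  expect_equal(max(abs(sig3)), 0, tolerance = 1e-12)
})

test_that("divergence norm matches element-wise exact integration", {
  em <- box_mesh(2, 1, 0.1)
  n <- nrow(em$nodes)
  expect_equal(divergence_norm(em, matrix(1, n, 2)), 0, tolerance = 1e-12)
  expect_equal(divergence_norm(em, cbind(em$nodes[, 1], -em$nodes[, 2])), 0,
               tolerance = 1e-10)
  # v = (x, y): div = 2 -> norm = 2 sqrt(total area)
  area <- sum(tri_signed_areas(em$nodes, em$tri))
  expect_equal(divergence_norm(em, em$nodes), 2 * sqrt(area),
               tolerance = 1e-10)
})

test_that("quiescent fluid with homogeneous Dirichlet data stays at rest", {
  em <- box_mesh(1, 1, 0.2)
  bcs <- list(list(tag = "inlet", type = "noslip"),
              list(tag = "outlet", type = "noslip"),
              list(tag = "wall", type = "noslip"))
  out <- solve_fluid_step(em, fluid_state(em), props_w, dt = 0.1, bcs = bcs)
  expect_equal(max(abs(out$v)), 0, tolerance = 1e-12)
  # pressure is the gauge constant
  expect_equal(max(abs(out$p - out$p[1])), 0, tolerance = 1e-8)
})

test_that("steady Poiseuille flow matches the closed form within 1 percent", {
  em <- box_mesh(4, 1, 0.1)
  dP <- 3.2
  bcs <- list(list(tag = "wall", type = "noslip"),
              list(tag = "inlet", type = "traction", pressure = dP),
              list(tag = "outlet", type = "traction", pressure = 0))
  out <- solve_fluid_step(em, fluid_state(em), props_w, dt = Inf, bcs = bcs)
  u_exact <- dP * 1^2 / (8 * props_w$mu * 4)
  i <- which(abs(em$nodes[, 1] - 2) < 1e-12 & abs(em$nodes[, 2] - 0.5) < 1e-12)
  expect_equal(out$v[i, 1], u_exact, tolerance = 0.01)
  expect_lt(max(abs(out$v[, 2])), 0.01 * u_exact)
})

test_that("Galilean shift of Dirichlet data shifts the solution uniformly", {
  em <- box_mesh(1, 1, 0.2)
  n <- nrow(em$nodes)
  base <- list(list(tag = "inlet", type = "dirichlet", value = c(0.3, 0.1)),
               list(tag = "outlet", type = "dirichlet", value = c(0.3, 0.1)),
               list(tag = "wall", type = "dirichlet", value = c(0.3, 0.1)))
  shift <- lapply(base, function(b) { b$value <- b$value + c(0.5, 0); b })
  o1 <- solve_fluid_step(em, fluid_state(em, v = matrix(rep(c(0.3, 0.1), each = n), n)),
                         props_w, dt = 0.05, bcs = base)
  o2 <- solve_fluid_step(em, fluid_state(em, v = matrix(rep(c(0.8, 0.1), each = n), n)),
                         props_w, dt = 0.05, bcs = shift)
  expect_equal(o2$v[, 1] - o1$v[, 1], rep(0.5, n), tolerance = 1e-8)
  expect_equal(o2$v[, 2], o1$v[, 2], tolerance = 1e-8)
})

test_that("semi-implicit operators reduce to the original ones when rho_bar = rho_f", {
  em <- box_mesh(2, 1, 0.2)
  n <- nrow(em$nodes)
  bcs <- list(list(tag = "wall", type = "noslip"),
              list(tag = "inlet", type = "dirichlet", value = c(1, 0)),
              list(tag = "outlet", type = "outflow"))
  st <- fluid_state(em)
  o1 <- solve_fluid_step(em, st, props_w, dt = 0.02, bcs = bcs)
  o2 <- solve_fluid_step(em, st, props_w, dt = 0.02, bcs = bcs,
                         rho_bar = rep(props_w$rho, n))
  expect_equal(o1$v, o2$v, tolerance = 1e-14)
  expect_equal(o1$p, o2$p, tolerance = 1e-12)
})

test_that("pseudo-compressible mode approaches the incompressible limit as kappa grows", {
  em <- box_mesh(2, 1, 0.2)
  n <- nrow(em$nodes)
  bcs <- list(list(tag = "wall", type = "noslip"),
              list(tag = "inlet", type = "dirichlet", value = c(1, 0)),
              list(tag = "outlet", type = "outflow"))
  st <- fluid_state(em)
  I <- as.numeric(em$nodes[, 1] > 0.8 & em$nodes[, 1] < 1.2)
  inc <- solve_fluid_step(em, st, props_w, dt = 0.02, bcs = bcs)
  stiff <- solve_fluid_step(em, st, props_w, dt = 0.02, bcs = bcs,
                            mode = "pseudo-compressible", kappa = 1e12,
                            indicator = I)
  soft <- solve_fluid_step(em, st, props_w, dt = 0.02, bcs = bcs,
                           mode = "pseudo-compressible", kappa = 1e2,
                           indicator = I)
  expect_lt(max(abs(stiff$v - inc$v)) / max(abs(inc$v)), 1e-6)
  # a soft artificial fluid really does deviate (the term is active)
  expect_gt(max(abs(soft$v - inc$v)) / max(abs(inc$v)), 1e-6)
})

test_that("velocity error decreases at first order or better under refinement", {
  dP <- 3.2
  err <- numeric(2)
  hs <- c(0.2, 0.1)
  for (k in 1:2) {
    em <- box_mesh(4, 1, hs[k])
    bcs <- list(list(tag = "wall", type = "noslip"),
                list(tag = "inlet", type = "traction", pressure = dP),
                list(tag = "outlet", type = "traction", pressure = 0))
    out <- solve_fluid_step(em, fluid_state(em), props_w, dt = Inf, bcs = bcs)
    u_ex <- dP / (2 * props_w$mu * 4) * em$nodes[, 2] * (1 - em$nodes[, 2])
    err[k] <- sqrt(mean((out$v[, 1] - u_ex)^2))
  }
  expect_gt(err[1] / err[2], 2^0.9)
})

test_that("a hopeless solve raises a solver-divergence condition", {
  em <- box_mesh(1, 1, 0.25)
  # absurd convection-dominated impulsive start with one iteration allowed
  bcs <- list(list(tag = "inlet", type = "dirichlet", value = c(1e4, 0)),
              list(tag = "wall", type = "noslip"),
              list(tag = "outlet", type = "outflow"))
  props_a <- fluid_properties(1, 1e-6)
  expect_error(
    solve_fluid_step(em, fluid_state(em), props_a, dt = 1, bcs = bcs,
                     picard_max = 2L),
    class = "solver_divergence")
})
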
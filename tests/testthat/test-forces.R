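# The three interaction-force definitions, the correction force and the
# coupling-error diagnostics.

force_fixture <- function(seed = 1) {
  set.seed(seed)
  em <- box_mesh(2, 1, 0.1)
  lm <- generate_disc_mesh(c(1, 0.5), 0.2, 0.07)
  n <- nrow(em$nodes)
  state <- fluid_state(em, v = cbind(0.1 * em$nodes[, 2] + 0.02 * rnorm(n),
                                     0.02 * rnorm(n)),
                       p = rnorm(n))
  kern <- build_kernel(em, lm)
  list(em = em, lm = lm, state = state, kern = kern)
}

test_that("explicit force reduces to the stress mismatch when densities match", {
  fx <- force_fixture()
  props <- fluid_properties(1, 0.5)
  mat <- material_model("linear-elastic", E = 50, nu = 0.3, rho = 1)
  sst <- solid_state(fx$lm)
  sst$u <- 0.01 * fx$lm$ref
  sig <- solid_stress(fx$lm, mat, sst)
  divf <- fluid_stress_divergence_at_solid(fx$em, fx$state, props, fx$kern,
                                           fx$lm)
  accel <- matrix(rnorm(2 * nrow(fx$lm$ref)), ncol = 2)
  f_exp <- fsi_force_explicit(fx$lm, mat, sig, divf, accel, rho_f = 1,
                              g = c(0, -980))
  f_semi <- fsi_force_semi_implicit(fx$lm, sig, divf)
  # rho_s = rho_f: inertia and gravity terms vanish identically
  expect_equal(f_exp, f_semi, tolerance = 1e-12)
})

test_that("gravity enters the explicit force as (rho_s - rho_f) g per nodal volume", {
  fx <- force_fixture()
  mat <- material_model("linear-elastic", E = 50, nu = 0.3, rho = 2.5)
  m <- nrow(fx$lm$tri)
  zero_sig <- matrix(0, m, 3)
  zero_divf <- matrix(0, nrow(fx$lm$ref), 2)
  zero_acc <- matrix(0, nrow(fx$lm$ref), 2)
  f <- fsi_force_explicit(fx$lm, mat, zero_sig, zero_divf, zero_acc,
                          rho_f = 1, g = c(0, -980))
  ms <- ifem2d:::lumped_areas(fx$lm$ref, fx$lm$tri)
  expect_equal(f[, 2], (2.5 - 1) * (-980) * ms, tolerance = 1e-12)
  expect_equal(max(abs(f[, 1])), 0)
})

test_that("semi-implicit force drops gravity entirely", {
  fx <- force_fixture()
  m <- nrow(fx$lm$tri)
  f <- fsi_force_semi_implicit(fx$lm, matrix(0, m, 3),
                               matrix(0, nrow(fx$lm$ref), 2))
  expect_equal(max(abs(f)), 0)
})

test_that("correction force vanishes for matching fields and recovers rho_s a", {
  fx <- force_fixture()
  mat <- material_model("linear-elastic", E = 50, nu = 0.3, rho = 3)
  ns <- nrow(fx$lm$ref)
  dv <- matrix(rnorm(2 * ns), ncol = 2)
  expect_equal(max(abs(correction_force(fx$lm, mat, dv, dv))), 0)
  # fluid at rest, solid uniformly accelerating at a: f = rho_s a * volume
  a <- c(3, -2)
  f <- correction_force(fx$lm, mat,
                        matrix(rep(a, each = ns), ncol = 2),
                        matrix(0, ns, 2))
  ms <- ifem2d:::lumped_areas(fx$lm$ref, fx$lm$tri)
  expect_equal(f[, 1], 3 * 3 * ms, tolerance = 1e-14)
  expect_equal(f[, 2], 3 * (-2) * ms, tolerance = 1e-14)
})

test_that("modified force is the exact sum of its parts on random states", {
  for (seed in 1:5) {
    fx <- force_fixture(seed)
    mat <- material_model("viscoelastic", E = 80, nu = 0.4, rho = 2,
                          eta = 0.3)
    props <- fluid_properties(1.2, 0.8)
    ns <- nrow(fx$lm$ref)
    sst <- solid_state(fx$lm,
                       u = matrix(rnorm(2 * ns, sd = 1e-3), ncol = 2),
                       v = matrix(rnorm(2 * ns), ncol = 2))
    sig <- solid_stress(fx$lm, mat, sst)
    divf <- fluid_stress_divergence_at_solid(fx$em, fx$state, props,
                                             fx$kern, fx$lm)
    f_dv <- correction_force(fx$lm, mat,
                             matrix(rnorm(2 * ns), ncol = 2),
                             matrix(rnorm(2 * ns), ncol = 2))
    f_mod <- fsi_force_modified(fx$lm, sig, divf, f_dv)
    f_semi <- fsi_force_semi_implicit(fx$lm, sig, divf)
    expect_equal(f_mod, f_semi + f_dv, tolerance = 1e-12)
    # zero state gives zero force
    f0 <- fsi_force_modified(fx$lm, 0 * sig, 0 * divf, 0 * f_dv)
    expect_equal(max(abs(f0)), 0)
  }
})

test_that("fluid material derivative matches finite differences for steady fields", {
  em <- box_mesh(2, 1, 0.1)
  n <- nrow(em$nodes)
  # steady nonuniform field v = (0.2 + 0.1 x, 0): Dv/Dt = (v.grad)v =
  # (0.1 (0.2 + 0.1 x), 0)
  v <- cbind(0.2 + 0.1 * em$nodes[, 1], 0)
  s1 <- fluid_state(em, v = v)
  s0 <- fluid_state(em, v = v)
  dv <- fluid_material_derivative(em, s1, s0, dt = 0.01)
  interior <- em$nodes[, 1] > 0.2 & em$nodes[, 1] < 1.8 &
    em$nodes[, 2] > 0.2 & em$nodes[, 2] < 0.8
  expect_equal(dv[interior, 1], 0.1 * (0.2 + 0.1 * em$nodes[interior, 1]),
               tolerance = 0.02)
  expect_equal(max(abs(dv[interior, 2])), 0, tolerance = 1e-10)
})

test_that("coupling-error ratios reproduce the diagnostic definitions", {
  props_air <- fluid_properties(1.3e-3, 1.8e-4)
  mat <- material_model("linear-elastic", E = 1e4, nu = 0.3, rho = 1.3)
  ce <- coupling_error_estimate(mat, props_air, dt = 1e-4)
  expect_equal(ce$density_ratio, 1.3 / 1.3e-3 - 1, tolerance = 1e-12)
  expect_equal(ce$stiffness_ratio, 1e4 / 1.3e-3, tolerance = 1e-12)
  ces <- coupling_error_estimate(mat, props_air, dt = 1e-4,
                                 semi_implicit = TRUE)
  expect_equal(ces$stiffness_ratio, 1e4 / 1.3, tolerance = 1e-12)
  # the semi-implicit stiffness ratio is smaller whenever rho_s > rho_f
  expect_lt(ces$stiffness_ratio, ce$stiffness_ratio)
  # matched densities, no gravity: density and gravity ratios vanish
  matm <- material_model("linear-elastic", E = 10, nu = 0.3, rho = 1)
  cem <- coupling_error_estimate(matm, fluid_properties(1, 1), dt = 0.1)
  expect_equal(cem$density_ratio, 0)
  expect_equal(cem$gravity_ratio, 0)
  # paper-style density ratio 1000 -> ratio 999
  mat1k <- material_model("linear-elastic", E = 10, nu = 0.3, rho = 1000)
  expect_equal(coupling_error_estimate(mat1k, fluid_properties(1, 1),
                                       dt = 0.1)$density_ratio, 999)
})
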
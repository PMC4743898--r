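# Lagrangian solid: constitutive models, strain/stress evaluation, internal
# (weak-form divergence) forces, and implicit structural dynamics for the
# mIFEM path.  Plane strain is assumed for all 2D solids; linear and
# viscoelastic kinds use the infinitesimal strain measure (no co-rotation:
# valid for small strains), the Mooney-Rivlin kind uses the full deformation
# gradient.

#' Solid material model
#'
#' @param kind `"linear-elastic"`, `"viscoelastic"` (Kelvin-Voigt) or
#'   `"mooney-rivlin"`.
#' @param E Young's modulus (dyn/cm^2).  1 kPa = 1e4 dyn/cm^2.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @param rho solid density rho^s (g/cm^3).
#' @param eta viscosity of the Kelvin-Voigt term (dyn s/cm^2); the viscous
#'   stress is `sigma_v = eta * strain_rate`, componentwise on the tensor
#'   components.
#' @param kappa compressibility modulus kappa^s (dyn/cm^2); defaults to the
#'   plane-strain bulk modulus `E / (2 (1 + nu) (1 - 2 nu))`.
#' @param strain_cap saturation bound on the strain components entering the
#'   stress evaluation (default `Inf`, i.e. off).  A finite cap keeps the
#'   restoring force direction but bounds its magnitude once an element is
#'   deformed beyond the small-strain validity range, so a locally folded
#'   element cannot inject unbounded forces; runs using it are qualitative
#'   in such regions.
#' @param c10,c01 Mooney-Rivlin coefficients (dyn/cm^2), used only by that
#'   kind.
#' @return object of class `material_model`.  The equivalent stiffness `K`
#'   used in coupling-error ratios is `E`.
#' @export
material_model <- function(kind = c("linear-elastic", "viscoelastic",
                                    "mooney-rivlin"),
                           E, nu, rho, eta = 0, kappa = NULL,
                           strain_cap = Inf, c10 = NULL, c01 = NULL) {
  kind <- match.arg(kind)
  if (rho <= 0) stop("solid density must be positive")
  if (nu <= -1 || nu >= 0.5) stop("Poisson ratio must be in (-1, 0.5)")
  if (E <= 0) stop("Young's modulus must be positive")
  if (is.null(kappa)) kappa <- E / (2 * (1 + nu) * (1 - 2 * nu))
  if (kappa <= 0) stop("kappa must be positive")
  if (kind == "mooney-rivlin") {
    mu_s <- E / (2 * (1 + nu))
    if (is.null(c10)) c10 <- mu_s / 2
    if (is.null(c01)) c01 <- 0
  }
  structure(list(kind = kind, E = E, nu = nu, rho = rho, eta = eta,
                 kappa = kappa, K = E, strain_cap = strain_cap,
                 c10 = c10, c01 = c01),
            class = "material_model")
}

# plane-strain elasticity matrix in engineering Voigt form
# (exx, eyy, gxy = 2 exy) -> (sxx, syy, sxy)
elastic_matrix <- function(mat) {
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu_s <- mat$E / (2 * (1 + mat$nu))
  matrix(c(lam + 2 * mu_s, lam, 0,
           lam, lam + 2 * mu_s, 0,
           0, 0, mu_s), 3, 3)
}

# Kelvin-Voigt viscosity matrix in engineering form: sigma_v = eta * edot
# (tensor components), i.e. sxy = eta * exy = eta * gxy / 2
viscous_matrix <- function(mat) {
  diag(c(mat$eta, mat$eta, mat$eta / 2))
}

#' Solid state
#'
#' Displacement, velocity and acceleration attached to solid nodes; the
#' current coordinates are `ref + u` at all times.
#' @param lm a `lagrangian_mesh`.
#' @param u,v,a n x 2 matrices (cm, cm/s, cm/s^2), defaulting to zero.
#' @export
solid_state <- function(lm, u = NULL, v = NULL, a = NULL) {
  n <- nrow(lm$ref)
  zero <- function(x) if (is.null(x)) matrix(0, n, 2) else as.matrix(x)
  structure(list(u = zero(u), v = zero(v), a = zero(a)),
            class = "solid_state")
}

solid_cur <- function(lm, state) {
  lm$cur <- lm$ref + state$u
  lm
}

#' Infinitesimal strain per element
#'
#' Symmetric small-strain tensor from the constant P1 gradients on the
#' reference configuration.
#' @param lm a `lagrangian_mesh`.
#' @param u nodal displacement, n x 2.
#' @param check_inversion raise an error when any current element area is
#'   non-positive (disable only when a strain cap is in force).
#' @return m x 3 matrix with columns `exx`, `eyy`, `exy` (tensor shear).
#' @export
compute_strain <- function(lm, u, check_inversion = TRUE) {
  fd <- fem_element_data(lm$ref, lm$tri)
  tri <- lm$tri
  if (check_inversion && any(tri_signed_areas(lm$ref + u, tri) <= 0))
    stop("element inversion: negative current area")
  uxx <- rowSums(fd$dNx * matrix(u[tri, 1], ncol = 3))
  uxy <- rowSums(fd$dNy * matrix(u[tri, 1], ncol = 3))
  uyx <- rowSums(fd$dNx * matrix(u[tri, 2], ncol = 3))
  uyy <- rowSums(fd$dNy * matrix(u[tri, 2], ncol = 3))
  cbind(exx = uxx, eyy = uyy, exy = 0.5 * (uxy + uyx))
}

# deformation gradient per element (m x 4: F11, F12, F21, F22)
deformation_gradient <- function(lm, u) {
  fd <- fem_element_data(lm$ref, lm$tri)
  tri <- lm$tri
  cbind(1 + rowSums(fd$dNx * matrix(u[tri, 1], ncol = 3)),
        rowSums(fd$dNy * matrix(u[tri, 1], ncol = 3)),
        rowSums(fd$dNx * matrix(u[tri, 2], ncol = 3)),
        1 + rowSums(fd$dNy * matrix(u[tri, 2], ncol = 3)))
}

#' Constitutive stress
#'
#' Plane-strain isotropic Hooke law plus a Kelvin-Voigt viscous term for the
#' small-strain kinds; the Mooney-Rivlin kind ignores `eps`/`eps_dot` and
#' computes the Cauchy stress from the deformation gradient `defgrad`
#' (plane-strain compressible Mooney-Rivlin with a volumetric penalty
#' `kappa (J - 1)`).
#'
#' @param mat a `material_model`.
#' @param eps m x 3 strain (columns exx, eyy, exy).
#' @param eps_dot m x 3 strain rate, or `NULL` for zero.
#' @param defgrad m x 4 deformation gradient (`mooney-rivlin` only).
#' @return m x 3 stress matrix (sxx, syy, sxy), dyn/cm^2.
#' @export
constitutive_stress <- function(mat, eps, eps_dot = NULL, defgrad = NULL) {
  if (mat$kind %in% c("linear-elastic", "viscoelastic")) {
    D <- elastic_matrix(mat)
    ev <- cbind(eps[, 1], eps[, 2], 2 * eps[, 3])
    sig <- ev %*% t(D)
    if (!is.null(eps_dot) && mat$eta > 0) {
      H <- viscous_matrix(mat)
      sig <- sig + cbind(eps_dot[, 1], eps_dot[, 2], 2 * eps_dot[, 3]) %*% t(H)
    }
    colnames(sig) <- c("sxx", "syy", "sxy")
    return(sig)
  }
  if (mat$kind == "mooney-rivlin") {
    if (is.null(defgrad)) stop("mooney-rivlin stress needs the deformation gradient")
    F11 <- defgrad[, 1]; F12 <- defgrad[, 2]
    F21 <- defgrad[, 3]; F22 <- defgrad[, 4]
    J <- F11 * F22 - F12 * F21
    # left Cauchy-Green (plane strain: out-of-plane stretch 1, b33 = 1)
    b11 <- F11^2 + F12^2
    b22 <- F21^2 + F22^2
    b12 <- F11 * F21 + F12 * F22
    I1 <- b11 + b22 + 1
    # 3D Cauchy stress for compressible MR (neo-Hooke-type volumetric term):
    # sigma = (2/J) [ (c10 + c01 I1) b - c01 b.b ] + vol, deviatoric-projected
    bb11 <- b11^2 + b12^2
    bb22 <- b12^2 + b22^2
    bb12 <- b12 * (b11 + b22)
    s11 <- 2 / J * ((mat$c10 + mat$c01 * I1) * b11 - mat$c01 * bb11)
    s22 <- 2 / J * ((mat$c10 + mat$c01 * I1) * b22 - mat$c01 * bb22)
    s12 <- 2 / J * ((mat$c10 + mat$c01 * I1) * b12 - mat$c01 * bb12)
    s33 <- 2 / J * ((mat$c10 + mat$c01 * I1) * 1 - mat$c01 * 1)
    trs <- (s11 + s22 + s33) / 3
    p <- mat$kappa * (J - 1)
    cbind(sxx = s11 - trs + p, syy = s22 - trs + p, sxy = s12)
  }
}

#' Internal nodal forces from an element stress field
#'
#' Weak-form divergence of the solid stress: integrated nodal loads equal to
#' minus the gradient of the strain energy for the elastic part; they sum to
#' zero in the absence of boundary traction.
#'
#' @param lm a `lagrangian_mesh`.
#' @param sigma m x 3 element stress.
#' @param current use the current instead of the reference configuration for
#'   the integration (finite-strain kinds).
#' @return n x 2 matrix of nodal forces (dyn, per unit depth).
#' @export
internal_force <- function(lm, sigma, current = FALSE) {
  nodes <- if (current) lm$cur else lm$ref
  weak_divergence(nodes, lm$tri, sigma)
}

# assemble the sparse stiffness-type matrix sum_e A B^T D B for a 3x3
# engineering-form material matrix D; an element-wise stiffness scale
# (lm$stiffness_scale, e.g. layered materials) multiplies the integrand
assemble_solid_matrix <- function(lm, D, scaled = TRUE) {
  fd <- fem_element_data(lm$ref, lm$tri)
  tri <- lm$tri
  n <- nrow(lm$ref)
  A <- fd$area
  if (scaled && !is.null(lm$stiffness_scale)) A <- A * lm$stiffness_scale
  # B rows: exx = dNx u, eyy = dNy v, gxy = dNy u + dNx v
  Bu <- list(x = fd$dNx, y = fd$dNy)
  trip_i <- list(); trip_j <- list(); trip_x <- list(); nt <- 0L
  add <- function(i, j, x) {
    nt <<- nt + 1L
    trip_i[[nt]] <<- i; trip_j[[nt]] <<- j; trip_x[[nt]] <<- x
  }
  for (a in 1:3) for (b in 1:3) {
    ia <- tri[, a]; ib <- tri[, b]
    bxa <- fd$dNx[, a]; bya <- fd$dNy[, a]
    bxb <- fd$dNx[, b]; byb <- fd$dNy[, b]
    # K_uu = A (bxa D11 bxb + bya D33 byb)
    add(ia, ib, A * (bxa * D[1, 1] * bxb + bya * D[3, 3] * byb))
    add(ia, n + ib, A * (bxa * D[1, 2] * byb + bya * D[3, 3] * bxb))
    add(n + ia, ib, A * (bya * D[2, 1] * bxb + bxa * D[3, 3] * byb))
    add(n + ia, n + ib, A * (bya * D[2, 2] * byb + bxa * D[3, 3] * bxb))
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(2L * n, 2L * n))
}

# nodal loads from solid traction bcs: list(edges = 2-col matrix of node
# pairs, value = c(tx, ty) or function(x, y))
solid_traction_loads <- function(lm, tractions) {
  n <- nrow(lm$ref)
  F <- matrix(0, n, 2)
  for (tr in tractions) {
    e <- tr$edges
    for (k in seq_len(nrow(e))) {
      p1 <- lm$ref[e[k, 1], ]; p2 <- lm$ref[e[k, 2], ]
      len <- sqrt(sum((p2 - p1)^2))
      val <- if (is.function(tr$value))
        as.numeric(tr$value((p1[1] + p2[1]) / 2, (p1[2] + p2[2]) / 2))
      else as.numeric(tr$value)
      F[e[k, 1], ] <- F[e[k, 1], ] + val * len / 2
      F[e[k, 2], ] <- F[e[k, 2], ] + val * len / 2
    }
  }
  F
}

# expand solid bc spec into fixed dof indices/values
solid_dirichlet <- function(lm, bcs) {
  n <- nrow(lm$ref)
  idx <- integer(0); val <- numeric(0)
  for (bc in bcs$dirichlet %||% list()) {
    nodes <- bc$nodes
    comp <- bc$comp %||% c(1L, 2L)    # constrained components (1 = x, 2 = y)
    uval <- if (is.null(bc$value)) matrix(0, length(nodes), 2) else
      matrix(as.numeric(bc$value), length(nodes), 2)
    if (1L %in% comp) { idx <- c(idx, nodes); val <- c(val, uval[, 1]) }
    if (2L %in% comp) { idx <- c(idx, n + nodes); val <- c(val, uval[, 2]) }
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], val = val[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Static solid equilibrium solve
#'
#' Solves `K u = F` for a small-strain material under Dirichlet constraints
#' and boundary tractions.  Used for patch tests and as the degenerate limit
#' of the dynamic solve.
#'
#' @param lm a `lagrangian_mesh`.
#' @param mat a small-strain `material_model`.
#' @param bcs list with optional `dirichlet` (list of `list(nodes, value)`)
#'   and `traction` (list of `list(edges, value)`) entries.
#' @param f_ext additional integrated nodal loads (n x 2), or `NULL`.
#' @return `solid_state` with the equilibrium displacement.
#' @export
solve_solid_static <- function(lm, mat, bcs, f_ext = NULL) {
  if (mat$kind == "mooney-rivlin")
    stop("static solve supports small-strain kinds only")
  n <- nrow(lm$ref)
  K <- assemble_solid_matrix(lm, elastic_matrix(mat))
  F <- solid_traction_loads(lm, bcs$traction %||% list())
  if (!is.null(f_ext)) F <- F + f_ext
  rhs <- c(F[, 1], F[, 2])
  fix <- solid_dirichlet(lm, bcs)
  sol <- constrained_solve(K, rhs, fix$idx, fix$val)
  solid_state(lm, u = cbind(sol[seq_len(n)], sol[n + seq_len(n)]))
}

constrained_solve <- function(K, rhs, idx, val) {
  ndof <- length(rhs)
  if (length(idx)) {
    # move prescribed values to the RHS, then zero rows/cols and set identity
    rhs <- rhs - as.numeric(K[, idx, drop = FALSE] %*% val)
    K[idx, ] <- 0
    K[, idx] <- 0
    K <- K + Matrix::sparseMatrix(i = idx, j = idx, x = 1, dims = dim(K))
    rhs[idx] <- val
  }
  as.numeric(Matrix::solve(K, rhs))
}

#' Implicit solid dynamics step (Newmark)
#'
#' Advances `rho_s a = div(sigma) + loads` one step with the trapezoidal
#' Newmark scheme (beta = 1/4, gamma = 1/2, unconditionally stable, no
#' algorithmic damping).  Mass is lumped; Kelvin-Voigt viscosity enters as a
#' damping matrix with the same sparsity as the stiffness.
#'
#' @param lm a `lagrangian_mesh`.
#' @param state previous `solid_state`.
#' @param mat a small-strain `material_model`.
#' @param bcs boundary conditions as in [solve_solid_static()]; Dirichlet
#'   values are *total* displacements to impose at the end of the step.
#' @param dt time step (s).
#' @param f_ext additional integrated nodal loads (n x 2), or `NULL`.
#' @param beta,gamma Newmark parameters.
#' @return new `solid_state` (with updated `u`, `v`, `a`).
#' @export
solve_solid_dynamics <- function(lm, state, mat, bcs, dt, f_ext = NULL,
                                 beta = 0.25, gamma = 0.5) {
  if (mat$kind == "mooney-rivlin")
    stop("dynamic solve supports small-strain kinds only")
  n <- nrow(lm$ref)
  K <- assemble_solid_matrix(lm, elastic_matrix(mat))
  C <- if (mat$eta > 0)
    assemble_solid_matrix(lm, viscous_matrix(mat), scaled = FALSE) else NULL
  mlump <- mat$rho * lumped_areas(lm$ref, lm$tri)
  Mdiag <- c(mlump, mlump)
  F <- solid_traction_loads(lm, bcs$traction %||% list())
  if (!is.null(f_ext)) F <- F + f_ext
  rhs <- c(F[, 1], F[, 2])
  u0 <- c(state$u[, 1], state$u[, 2])
  v0 <- c(state$v[, 1], state$v[, 2])
  a0 <- c(state$a[, 1], state$a[, 2])
  c0 <- 1 / (beta * dt^2)
  upred <- u0 + dt * v0 + dt^2 / 2 * (1 - 2 * beta) * a0
  vpred <- v0 + (1 - gamma) * dt * a0
  Keff <- K + Matrix::Diagonal(x = Mdiag * c0)
  rhs_eff <- rhs + Mdiag * c0 * upred
  if (!is.null(C)) {
    Keff <- Keff + gamma * dt * c0 * C
    rhs_eff <- rhs_eff + as.numeric(C %*% (gamma * dt * c0 * upred - vpred))
  }
  fix <- solid_dirichlet(lm, bcs)
  u1 <- constrained_solve(Keff, rhs_eff, fix$idx, fix$val)
  a1 <- c0 * (u1 - upred)
  v1 <- vpred + gamma * dt * a1
  unew <- cbind(u1[seq_len(n)], u1[n + seq_len(n)])
  if (any(tri_signed_areas(lm$ref + unew, lm$tri) <= 0))
    stop(structure(class = c("step_rejection", "error", "condition"),
                   list(message = "element inversion in solid step",
                        call = NULL)))
  solid_state(lm, u = unew,
              v = cbind(v1[seq_len(n)], v1[n + seq_len(n)]),
              a = cbind(a1[seq_len(n)], a1[n + seq_len(n)]))
}

#' Advance solid positions with the current velocity
#'
#' The explicit/semi-implicit position update `u <- u + v dt`; current
#' coordinates follow as `ref + u`.
#' @param state a `solid_state`.
#' @param dt time step (s).
#' @return updated `solid_state`.
#' @export
update_positions <- function(state, dt) {
  state$u <- state$u + state$v * dt
  state
}

#' Element stress of the current solid state
#'
#' Convenience wrapper choosing the strain measure by material kind.
#' @param lm mesh; @param mat material; @param state `solid_state`.
#' @return m x 3 stress matrix.
#' @export
solid_stress <- function(lm, mat, state) {
  if (mat$kind == "mooney-rivlin") {
    constitutive_stress(mat, NULL, defgrad = deformation_gradient(lm, state$u))
  } else {
    cap <- mat$strain_cap %||% Inf
    eps <- compute_strain(lm, state$u, check_inversion = !is.finite(cap))
    if (is.finite(cap)) eps <- pmin(pmax(eps, -cap), cap)
    epsd <- compute_strain_rate(lm, state$v)
    sig <- constitutive_stress(mat, eps, NULL)
    if (!is.null(lm$stiffness_scale)) sig <- sig * lm$stiffness_scale
    sig + constitutive_stress(mat, 0 * eps, epsd)
  }
}

# strain rate from nodal velocities (same operator as compute_strain)
compute_strain_rate <- function(lm, v) {
  fd <- fem_element_data(lm$ref, lm$tri)
  tri <- lm$tri
  vxx <- rowSums(fd$dNx * matrix(v[tri, 1], ncol = 3))
  vxy <- rowSums(fd$dNy * matrix(v[tri, 1], ncol = 3))
  vyx <- rowSums(fd$dNx * matrix(v[tri, 2], ncol = 3))
  vyy <- rowSums(fd$dNy * matrix(v[tri, 2], ncol = 3))
  cbind(exx = vxx, eyy = vyy, exy = 0.5 * (vxy + vyx))
}
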
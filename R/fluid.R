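# Stabilized equal-order (P1/P1) finite element solver for the incompressible
# Navier-Stokes equations on the fixed Eulerian mesh, with optional variable
# (effective) density and pseudo-compressible continuity in the artificial
# fluid.  Time discretization is implicit backward Euler; the convective term
# is linearized by Picard iteration; SUPG/PSPG residual stabilization makes
# the equal-order pair inf-sup stable.  The viscous term is kept in gradient
# (Laplacian) form, so traction-type boundary conditions impose the
# pseudo-traction -p n + mu (grad v) n of the do-nothing family.

#' Fluid properties
#' @param rho density rho^f (g/cm^3), positive.
#' @param mu dynamic viscosity (g/(cm s)), positive.
#' @param g body acceleration (cm/s^2), length-2 vector; defaults to zero.
#' @export
fluid_properties <- function(rho, mu, g = c(0, 0)) {
  if (rho <= 0 || mu <= 0) stop("fluid density and viscosity must be positive")
  structure(list(rho = rho, mu = mu, g = as.numeric(g)),
            class = "fluid_properties")
}

#' Fluid state
#' @param em fluid mesh.
#' @param v nodal velocity, n x 2 (cm/s); defaults to rest.
#' @param p nodal pressure (dyn/cm^2); defaults to zero.
#' @param t time (s).
#' @export
fluid_state <- function(em, v = NULL, p = NULL, t = 0) {
  n <- nrow(em$nodes)
  if (is.null(v)) v <- matrix(0, n, 2)
  if (is.null(p)) p <- rep(0, n)
  stopifnot(nrow(v) == n, length(p) == n)
  structure(list(v = v, p = p, t = t), class = "fluid_state")
}

#' Effective density field
#'
#' Blends fluid and solid density through the indicator field,
#' `rho_bar = rho_f + (rho_s - rho_f) I`, so that the semi-implicit momentum
#' equation carries the solid inertia inside the overlapped region.
#'
#' @param I indicator values per fluid node, each in `[0, 1]`.
#' @param rho_f,rho_s fluid and solid densities (g/cm^3).
#' @return nodal density vector.
#' @export
effective_density <- function(I, rho_f, rho_s) {
  if (any(I < -1e-12) || any(I > 1 + 1e-12))
    stop("indicator invariant violation: I outside [0, 1]")
  rho_f + (rho_s - rho_f) * pmin(pmax(I, 0), 1)
}

get_femdata <- function(em) {
  fd <- attr(em, "femdata")
  if (is.null(fd)) fd <- fem_element_data(em$nodes, em$tri)
  fd
}

#' Precompute and cache element data and the point locator on a mesh
#'
#' The Eulerian mesh is fixed, so shape-function gradients, lumped areas and
#' the spatial hash can be computed once up front.
#' @param em an `eulerian_mesh`.
#' @export
with_femdata <- function(em) {
  attr(em, "femdata") <- fem_element_data(em$nodes, em$tri)
  attr(em, "lumped") <- lumped_areas(em$nodes, em$tri)
  attr(em, "locator") <- build_point_locator(em)
  em
}

get_lumped <- function(em) {
  la <- attr(em, "lumped")
  if (is.null(la)) la <- lumped_areas(em$nodes, em$tri)
  la
}

#' Fluid Cauchy stress per element
#'
#' Newtonian closure `sigma = -p I + mu (grad v + grad v^T)` evaluated with
#' the element-constant P1 gradients and the element-mean pressure.
#'
#' @param em fluid mesh.
#' @param state a `fluid_state`.
#' @param props a `fluid_properties`.
#' @return m x 3 matrix with columns `sxx`, `syy`, `sxy`.
#' @export
fluid_stress <- function(em, state, props) {
  fd <- get_femdata(em)
  tri <- em$tri
  u <- state$v[, 1]; v <- state$v[, 2]
  ux <- rowSums(fd$dNx * matrix(u[tri], ncol = 3))
  uy <- rowSums(fd$dNy * matrix(u[tri], ncol = 3))
  vx <- rowSums(fd$dNx * matrix(v[tri], ncol = 3))
  vy <- rowSums(fd$dNy * matrix(v[tri], ncol = 3))
  pbar <- rowMeans(matrix(state$p[tri], ncol = 3))
  cbind(sxx = -pbar + 2 * props$mu * ux,
        syy = -pbar + 2 * props$mu * vy,
        sxy = props$mu * (uy + vx))
}

#' L2 norm of the discrete velocity divergence
#'
#' Diagnostic for the incompressibility constraint: element-wise exact
#' integration of the (element-constant) divergence of the P1 field.
#'
#' @param em fluid mesh.
#' @param v nodal velocity (n x 2) or a `fluid_state`.
#' @export
divergence_norm <- function(em, v) {
  if (inherits(v, "fluid_state")) v <- v$v
  fd <- get_femdata(em)
  tri <- em$tri
  div <- rowSums(fd$dNx * matrix(v[tri, 1], ncol = 3)) +
    rowSums(fd$dNy * matrix(v[tri, 2], ncol = 3))
  sqrt(sum(fd$area * div^2))
}

# scatter-add: sum x into n bins given by index vector ia
accum <- function(ia, x, n) {
  out <- numeric(n)
  r <- rowsum(x, ia)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

# weak-form nodal forces representing div(sigma) for an element stress field
# (columns sxx, syy, sxy): f_a = -sum_e A_e B_a^T sigma_e.  These are
# integrated nodal loads; for an elastic stress they equal -dE/du.
weak_divergence <- function(nodes, tri, sigma, fd = NULL) {
  if (is.null(fd)) fd <- fem_element_data(nodes, tri)
  n <- nrow(nodes)
  fx <- fy <- numeric(n)
  for (a in 1:3) {
    ia <- tri[, a]
    fx <- fx + accum(ia, -fd$area * (fd$dNx[, a] * sigma[, 1] +
                                       fd$dNy[, a] * sigma[, 3]), n)
    fy <- fy + accum(ia, -fd$area * (fd$dNx[, a] * sigma[, 3] +
                                       fd$dNy[, a] * sigma[, 2]), n)
  }
  cbind(fx, fy)
}

# collect Dirichlet velocity dofs and values from the bc list; a bc value
# may be a function of (x, y) or of (x, y, t) (e.g. a ramped inlet)
dirichlet_velocity <- function(em, bcs, t = 0) {
  n <- nrow(em$nodes)
  idx <- integer(0); val <- numeric(0)
  for (bc in bcs) {
    type <- bc$type
    if (!(type %in% c("dirichlet", "noslip"))) next
    nodes_tag <- em$tags[[bc$tag]]
    if (is.null(nodes_tag)) stop(sprintf("unknown boundary tag '%s'", bc$tag))
    if (type == "noslip") {
      vv <- matrix(0, length(nodes_tag), 2)
    } else if (is.function(bc$value)) {
      vv <- if (length(formals(bc$value)) >= 3L)
        bc$value(em$nodes[nodes_tag, 1], em$nodes[nodes_tag, 2], t)
      else bc$value(em$nodes[nodes_tag, 1], em$nodes[nodes_tag, 2])
      vv <- matrix(as.numeric(vv), ncol = 2)
    } else {
      vv <- matrix(rep(as.numeric(bc$value), each = length(nodes_tag)),
                   ncol = 2)
    }
    idx <- c(idx, nodes_tag, n + nodes_tag)
    val <- c(val, vv[, 1], vv[, 2])
  }
  # later bcs win on shared corner nodes
  ridx <- rev(idx); rval <- rev(val)
  keep <- !duplicated(ridx)
  list(idx = ridx[keep], val = rval[keep])
}

# nodal loads from traction boundary conditions; bc$pressure P imposes
# t = -P n (n outward) on the tagged edges, bc$value a fixed traction vector
traction_loads <- function(em, bcs) {
  n <- nrow(em$nodes)
  F <- matrix(0, n, 2)
  any_natural <- FALSE
  centroids <- (em$nodes[em$tri[, 1], , drop = FALSE] +
                em$nodes[em$tri[, 2], , drop = FALSE] +
                em$nodes[em$tri[, 3], , drop = FALSE]) / 3
  for (bc in bcs) {
    if (bc$type == "outflow") { any_natural <- TRUE; next }
    if (bc$type != "traction") next
    any_natural <- TRUE
    be <- em$boundary_edges
    sel <- which(be$tag == bc$tag)
    if (!length(sel)) stop(sprintf("unknown boundary tag '%s'", bc$tag))
    for (k in sel) {
      n1 <- be$n1[k]; n2 <- be$n2[k]
      p1 <- em$nodes[n1, ]; p2 <- em$nodes[n2, ]
      d <- p2 - p1
      len <- sqrt(sum(d^2))
      nrm <- c(d[2], -d[1]) / len
      # orient the normal away from the owning triangle's centroid
      own <- which(rowSums(matrix(em$tri %in% c(n1, n2),
                                  ncol = 3)) >= 2)[1]
      mid <- (p1 + p2) / 2
      if (sum(nrm * (mid - centroids[own, ])) < 0) nrm <- -nrm
      tr <- if (!is.null(bc$pressure)) -bc$pressure * nrm else
        as.numeric(bc$value)
      F[n1, ] <- F[n1, ] + tr * len / 2
      F[n2, ] <- F[n2, ] + tr * len / 2
    }
  }
  list(F = F, any_natural = any_natural)
}

#' Advance the fluid by one implicit time step
#'
#' Solves the stabilized weak form of the momentum/continuity system with
#' backward Euler in time and Picard linearization of convection.  The
#' momentum equation uses the nodal density field `rho_bar` when given (the
#' semi-implicit formulation, which also applies gravity as `rho_bar g`),
#' otherwise the constant fluid density — with `rho_bar` identical to
#' `rho_f` everywhere and no interaction force, the assembled operators of
#' the two forms coincide exactly.  In `pseudo-compressible` mode the
#' continuity equation gains the lumped term `(1/kappa) dp/dt I(x)` on nodes
#' where the indicator is positive, letting the pressure field accommodate
#' the volume change of the overlapped solid.
#'
#' @param em fluid mesh (cache element data with [with_femdata()] for speed).
#' @param state previous `fluid_state`.
#' @param props `fluid_properties`.
#' @param dt time step (s); `Inf` solves the steady problem.
#' @param bcs list of boundary conditions; each element is a list with
#'   `tag`, `type` (`"dirichlet"`, `"noslip"`, `"traction"`, `"outflow"`)
#'   and, as appropriate, `value` (velocity vector or `function(x, y)`, or a
#'   traction vector) or `pressure`.
#' @param fsi_force integrated nodal loads (n x 2) distributed from the
#'   solid, or `NULL`.
#' @param rho_bar nodal effective density (semi-implicit/mIFEM), or `NULL`.
#' @param mode `"incompressible"` or `"pseudo-compressible"`.
#' @param kappa solid compressibility modulus (dyn/cm^2) for the
#'   pseudo-compressible continuity term.
#' @param indicator nodal indicator field (needed in pseudo-compressible
#'   mode).
#' @param corr_mass mIFEM correction-force coupling: integrated solid mass
#'   distributed onto fluid nodes (g per node, length n).  When given, the
#'   term `rho_s (Dv^f/Dt)` of the correction force is discretized
#'   implicitly inside this solve (time part on the matrix diagonal,
#'   convective part from the Picard iterate), which is the stable
#'   realization of the same force.
#' @param corr_load the companion right-hand-side loads
#'   `rho_s Dv^s/Dt` distributed onto fluid nodes (n x 2).
#' @param picard_max,picard_tol Picard iteration controls (relative change
#'   of the solution vector).
#' @param picard_fail relative-change level above which a step that used up
#'   all Picard iterations is rejected as diverged (between `picard_tol`
#'   and this level the step is accepted as loosely converged).
#' @param gauge_node node whose pressure is pinned to zero when the boundary
#'   conditions contain no natural (traction/outflow) segment.
#' @return the new `fluid_state`, with attributes `iterations` and
#'   `div_norm`.
#' @export
solve_fluid_step <- function(em, state, props, dt, bcs,
                             fsi_force = NULL, rho_bar = NULL,
                             mode = c("incompressible", "pseudo-compressible"),
                             kappa = NULL, indicator = NULL,
                             corr_mass = NULL, corr_load = NULL,
                             picard_max = 20L, picard_tol = 1e-8,
                             picard_fail = 1e-2, gauge_node = 1L) {
  mode <- match.arg(mode)
  n <- nrow(em$nodes)
  fd <- get_femdata(em)
  tri <- em$tri
  A <- fd$area
  lump <- get_lumped(em)
  he <- sqrt(2 * A)
  idt <- if (is.finite(dt)) 1 / dt else 0
  rho_e <- if (is.null(rho_bar)) rep(props$rho, nrow(tri)) else
    rowMeans(matrix(rho_bar[tri], ncol = 3))
  mu <- props$mu
  g <- props$g
  if (is.null(fsi_force)) fsi_force <- matrix(0, n, 2)
  fdens <- fsi_force / lump                       # force density per node
  fde_x <- rowMeans(matrix(fdens[tri, 1], ncol = 3))
  fde_y <- rowMeans(matrix(fdens[tri, 2], ncol = 3))
  tl <- traction_loads(em, bcs)
  dirv <- dirichlet_velocity(em, bcs,
                             state$t + (if (is.finite(dt)) dt else 0))
  fix_gauge <- !tl$any_natural
  vold <- state$v; pold <- state$p
  uold_e <- rowMeans(matrix(vold[tri, 1], ncol = 3))
  vold_e <- rowMeans(matrix(vold[tri, 2], ncol = 3))
  if (mode == "pseudo-compressible") {
    if (is.null(kappa) || is.null(indicator))
      stop("pseudo-compressible mode needs kappa and indicator")
    if (idt == 0) stop("pseudo-compressible mode requires a finite dt")
    comp_diag <- (indicator > 1e-8) * lump / kappa * idt
  } else comp_diag <- numeric(n)

  ndof <- 3L * n
  iu <- seq_len(n); iv <- n + iu; ip <- 2L * n + iu
  vcur <- vold
  sol_prev <- c(vold[, 1], vold[, 2], pold)
  iters <- 0L
  resid_hist <- numeric(0)
  relax <- 1
  for (it in seq_len(picard_max)) {
    iters <- it
    wx <- rowMeans(matrix(vcur[tri, 1], ncol = 3))
    wy <- rowMeans(matrix(vcur[tri, 2], ncol = 3))
    wnorm <- sqrt(wx^2 + wy^2)
    nu_e <- mu / rho_e
    tau <- 1 / sqrt((2 * idt)^2 + (2 * wnorm / he)^2 + (12 * nu_e / he^2)^2)
    tau_m <- tau / rho_e
    trip_i <- list(); trip_j <- list(); trip_x <- list(); nt <- 0L
    add <- function(i, j, x) {
      nt <<- nt + 1L
      trip_i[[nt]] <<- i; trip_j[[nt]] <<- j; trip_x[[nt]] <<- x
    }
    rhs <- numeric(ndof)
    wgN <- lapply(1:3, function(b) wx * fd$dNx[, b] + wy * fd$dNy[, b])
    for (a in 1:3) {
      ia <- tri[, a]
      sa <- tau_m * wgN[[a]]                       # SUPG test weight
      # Galerkin + SUPG body/FSI-force RHS (x and y momentum)
      rhs[iu] <- rhs[iu] + accum(ia, A / 3 * (rho_e * g[1] + fde_x) +
                                   A * sa * (rho_e * g[1] + fde_x +
                                               rho_e * idt * uold_e), n)
      rhs[iv] <- rhs[iv] + accum(ia, A / 3 * (rho_e * g[2] + fde_y) +
                                   A * sa * (rho_e * g[2] + fde_y +
                                               rho_e * idt * vold_e), n)
      # PSPG RHS
      rhs[ip] <- rhs[ip] + accum(ia,
        A * tau_m * (fd$dNx[, a] * (rho_e * g[1] + fde_x +
                                      rho_e * idt * uold_e) +
                     fd$dNy[, a] * (rho_e * g[2] + fde_y +
                                      rho_e * idt * vold_e)), n)
      for (b in 1:3) {
        ib <- tri[, b]
        visc <- mu * A * (fd$dNx[, a] * fd$dNx[, b] +
                            fd$dNy[, a] * fd$dNy[, b])
        conv <- rho_e * A / 3 * wgN[[b]]
        mass <- rho_e * idt * A / 12 * (1 + (a == b))
        supg <- A * sa * rho_e * (wgN[[b]] + idt / 3)
        Kab <- visc + conv + mass + supg
        add(ia, ib, Kab)
        add(n + ia, n + ib, Kab)
        # pressure terms in momentum: Galerkin -(A/3) dN_a + SUPG
        add(ia, 2L * n + ib, -A / 3 * fd$dNx[, a] + A * sa * fd$dNx[, b])
        add(n + ia, 2L * n + ib, -A / 3 * fd$dNy[, a] + A * sa * fd$dNy[, b])
        # continuity + PSPG momentum-residual terms
        add(2L * n + ia, ib, A / 3 * fd$dNx[, b] +
              A * tau_m * fd$dNx[, a] * rho_e * (idt / 3 + wgN[[b]]))
        add(2L * n + ia, n + ib, A / 3 * fd$dNy[, b] +
              A * tau_m * fd$dNy[, a] * rho_e * (idt / 3 + wgN[[b]]))
        # PSPG pressure Laplacian
        add(2L * n + ia, 2L * n + ib,
            A * tau_m * (fd$dNx[, a] * fd$dNx[, b] +
                           fd$dNy[, a] * fd$dNy[, b]))
        # consistent-mass RHS of the momentum time term
        if (idt > 0) {
          rhs[iu] <- rhs[iu] + accum(ia, mass * vold[ib, 1], n)
          rhs[iv] <- rhs[iv] + accum(ia, mass * vold[ib, 2], n)
        }
      }
    }
    if (any(comp_diag > 0)) {
      add(ip, ip, comp_diag)
      rhs[ip] <- rhs[ip] + comp_diag * pold
    }
    if (!is.null(corr_mass)) {
      # implicit correction-force coupling: rho_s dv/dt on the diagonal,
      # convective part of Dv^f/Dt from the current Picard iterate
      add(iu, iu, corr_mass * idt)
      add(iv, iv, corr_mass * idt)
      convx_e <- wx * rowSums(fd$dNx * matrix(vcur[tri, 1], ncol = 3)) +
        wy * rowSums(fd$dNy * matrix(vcur[tri, 1], ncol = 3))
      convy_e <- wx * rowSums(fd$dNx * matrix(vcur[tri, 2], ncol = 3)) +
        wy * rowSums(fd$dNy * matrix(vcur[tri, 2], ncol = 3))
      cxn <- cyn <- numeric(n)
      for (a in 1:3) {
        cxn <- cxn + accum(tri[, a], A / 3 * convx_e, n)
        cyn <- cyn + accum(tri[, a], A / 3 * convy_e, n)
      }
      rhs[iu] <- rhs[iu] + corr_mass * (idt * vold[, 1] - cxn / lump) +
        (if (!is.null(corr_load)) corr_load[, 1] else 0)
      rhs[iv] <- rhs[iv] + corr_mass * (idt * vold[, 2] - cyn / lump) +
        (if (!is.null(corr_load)) corr_load[, 2] else 0)
    }
    rhs[iu] <- rhs[iu] + fsi_force[, 1] + tl$F[, 1]
    rhs[iv] <- rhs[iv] + fsi_force[, 2] + tl$F[, 2]
    fixed <- dirv$idx
    fixval <- dirv$val
    if (fix_gauge) {
      fixed <- c(fixed, 2L * n + gauge_node)
      fixval <- c(fixval, 0)
    }
    II <- unlist(trip_i); JJ <- unlist(trip_j); XX <- unlist(trip_x)
    keep <- !(II %in% fixed)
    M <- Matrix::sparseMatrix(i = c(II[keep], fixed),
                              j = c(JJ[keep], fixed),
                              x = c(XX[keep], rep(1, length(fixed))),
                              dims = c(ndof, ndof))
    rhs[fixed] <- fixval
    sol <- as.numeric(Matrix::solve(M, rhs))
    dsol <- sqrt(sum((sol - sol_prev)^2)) / max(sqrt(sum(sol^2)), 1e-300)
    # adaptive under-relaxation: damp the update when the iteration
    # oscillates (convection-dominated or strong density contrast)
    nres <- length(resid_hist)
    if (nres >= 1L && dsol > resid_hist[nres]) relax <- max(0.15, relax * 0.5)
    else relax <- min(1, relax * 1.25)
    resid_hist <- c(resid_hist, dsol)
    sol <- relax * sol + (1 - relax) * sol_prev
    sol_prev <- sol
    vcur <- cbind(sol[iu], sol[iv])
    if (!all(is.finite(sol)))
      stop(structure(class = c("solver_divergence", "error", "condition"),
                     list(message = "fluid solution is not finite",
                          call = NULL)))
    if (dsol < picard_tol) break
    if (it == picard_max && dsol > picard_fail)
      stop(structure(class = c("solver_divergence", "error", "condition"),
                     list(message = sprintf(
                       paste0("fluid solver did not converge (relative ",
                              "change %.3e after %d Picard iterations; ",
                              "history %s)"), dsol, it,
                       paste(signif(resid_hist, 3), collapse = " ")),
                       call = NULL)))
  }
  out <- fluid_state(em, v = vcur, p = sol_prev[ip],
                     t = state$t + (if (is.finite(dt)) dt else 0))
  attr(out, "iterations") <- iters
  attr(out, "div_norm") <- divergence_norm(em, vcur)
  out
}
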
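# Simulation container and the three time-stepping orchestrators.  All
# three advance one staggered pass per time step (no sub-iteration to
# mutual convergence), following the algorithm outlines: forces are
# evaluated on the solid of the previous step, distributed, the fluid is
# solved implicitly, and the solid is moved.

#' Create an IFEM simulation
#'
#' Bundles the meshes, properties, boundary conditions and algorithm choice
#' into a simulation object advanced by [step_sim()] / [run_sim()].
#'
#' @param em Eulerian fluid mesh.
#' @param lm Lagrangian solid mesh (current coords = reference at t = 0).
#' @param props `fluid_properties`.
#' @param mat `material_model` of the solid.
#' @param dt time step (s).
#' @param fluid_bcs boundary-condition list for [solve_fluid_step()].
#' @param algorithm `"ifem"` (explicit), `"semi_implicit"` or `"mifem"`.
#' @param kernel_kind interpolation kernel kind ([build_kernel()]).
#' @param solid_bcs mIFEM only: list with `fixed_nodes` (Dirichlet-fixed
#'   solid nodes, e.g. a wall attachment, may be empty) and `fsi`
#'   (`"traction"` to load the wet boundary with the interpolated fluid
#'   traction, `"dirichlet"` to prescribe boundary displacement increments
#'   `v^f dt`).
#' @param correction mIFEM only: include the correction force (default
#'   `TRUE`).
#' @param pseudo_compressible mIFEM only: use the pseudo-compressible
#'   continuity equation in the overlap (default `TRUE`).
#' @param indicator_band transition band width for [solve_indicator()].
#' @param cfl_warn warn when `max|v| dt / h` exceeds this value.
#' @param picard_max,picard_tol,picard_fail Picard controls forwarded to
#'   [solve_fluid_step()].
#' @return object of class `ifem_sim`.
#' @export
ifem_sim <- function(em, lm, props, mat, dt, fluid_bcs,
                     algorithm = c("ifem", "semi_implicit", "mifem"),
                     kernel_kind = "fe-shape",
                     solid_bcs = list(fixed_nodes = integer(0),
                                      fsi = "traction"),
                     correction = TRUE, pseudo_compressible = TRUE,
                     indicator_band = NULL, cfl_warn = 1,
                     picard_max = 25L, picard_tol = 1e-8, picard_fail = 1e-2) {
  algorithm <- match.arg(algorithm)
  if (dt <= 0) stop("dt must be positive")
  if (is.null(attr(em, "femdata"))) em <- with_femdata(em)
  sim <- structure(list(
    em = em, lm = lm, props = props, mat = mat, dt = dt,
    fluid_bcs = fluid_bcs, algorithm = algorithm,
    kernel_kind = kernel_kind, solid_bcs = solid_bcs,
    correction = correction, pseudo_compressible = pseudo_compressible,
    indicator_band = indicator_band, cfl_warn = cfl_warn,
    picard_max = picard_max, picard_tol = picard_tol,
    picard_fail = picard_fail,
    fluid = fluid_state(em), fluid_prev = NULL,
    solid = solid_state(lm), vs_prev = NULL,
    indicator = NULL, f_fsi_f = NULL, f_fsi_s = NULL,
    step = 0L, cfl_warned = FALSE,
    history = list()), class = "ifem_sim")
  sim
}

#' @export
print.ifem_sim <- function(x, ...) {
  cat(sprintf("<ifem_sim> %s, step %d, t = %g s\n", x$algorithm, x$step,
              x$fluid$t))
  invisible(x)
}

sim_diagnostics <- function(sim, kernel, clip_eps = NA_real_,
                            noslip = NA_real_) {
  cons <- if (!is.null(sim$f_fsi_f))
    max(abs(colSums(sim$f_fsi_f) - colSums(sim$f_fsi_s))) else 0
  h_f <- mesh_h(sim$em$nodes, sim$em$tri)
  maxv <- max(abs(sim$fluid$v))
  cfl <- maxv * sim$dt / h_f
  areas <- tri_signed_areas(sim$lm$cur, sim$lm$tri)
  cen <- colMeans(sim$lm$cur)
  data.frame(step = sim$step, t = sim$fluid$t,
             div_norm = as.numeric(attr(sim$fluid, "div_norm") %||% NA),
             picard = as.integer(attr(sim$fluid, "iterations") %||% NA),
             conservation = cons, max_v = maxv, cfl = cfl,
             min_solid_area = min(areas),
             indicator_clip = clip_eps, noslip = noslip,
             centroid_x = cen[1], centroid_y = cen[2])
}

check_cfl <- function(sim) {
  if (sim$cfl_warned) return(sim)
  h_f <- mesh_h(sim$em$nodes, sim$em$tri)
  if (max(abs(sim$fluid$v)) * sim$dt / h_f > sim$cfl_warn) {
    warning(sprintf("CFL guard: max|v| dt / h = %.2f exceeds %.2f",
                    max(abs(sim$fluid$v)) * sim$dt / h_f, sim$cfl_warn))
    sim$cfl_warned <- TRUE
  }
  sim
}

solid_accel_estimate <- function(sim) {
  if (is.null(sim$vs_prev)) matrix(0, nrow(sim$lm$ref), 2)
  else (sim$solid$v - sim$vs_prev) / sim$dt
}

#' Advance one explicit IFEM step
#'
#' Steps: interaction force on solid nodes (previous configuration) ->
#' distribution to the fluid -> implicit fluid solve -> velocity
#' interpolation back to the solid (the solid velocity is *set* to the
#' interpolated fluid velocity) -> position update `u <- u + v dt`.
#'
#' @param sim an `ifem_sim`.
#' @return the advanced simulation.
#' @export
step_ifem <- function(sim) {
  kernel <- build_kernel(sim$em, sim$lm, sim$kernel_kind)
  sigma_s <- solid_stress(sim$lm, sim$mat, sim$solid)
  divf <- fluid_stress_divergence_at_solid(sim$em, sim$fluid, sim$props,
                                           kernel, sim$lm)
  accel <- solid_accel_estimate(sim)
  f_s <- fsi_force_explicit(sim$lm, sim$mat, sigma_s, divf, accel,
                            sim$props$rho, sim$props$g)
  f_f <- distribute_to_fluid(kernel, f_s)
  fluid_new <- solve_fluid_step(sim$em, sim$fluid, sim$props, sim$dt,
                                sim$fluid_bcs, fsi_force = f_f,
                                picard_max = sim$picard_max,
                                picard_tol = sim$picard_tol,
                                picard_fail = sim$picard_fail)
  vs <- interpolate_to_solid(kernel, fluid_new$v)
  sim$vs_prev <- sim$solid$v
  sim$solid$v <- vs
  old_cur <- sim$lm$cur
  sim$solid <- update_positions(sim$solid, sim$dt)
  cl <- clamp_into_domain(sim$em, old_cur, sim$lm$ref + sim$solid$u)
  if (length(cl$clamped))
    sim$solid$u[cl$clamped, ] <- cl$pts[cl$clamped, , drop = FALSE] -
      sim$lm$ref[cl$clamped, , drop = FALSE]
  sim$lm$cur <- sim$lm$ref + sim$solid$u
  sim$fluid_prev <- sim$fluid
  sim$fluid <- fluid_new
  sim$f_fsi_s <- f_s; sim$f_fsi_f <- f_f
  sim$step <- sim$step + 1L
  sim <- check_cfl(sim)
  sim$history[[length(sim$history) + 1L]] <- sim_diagnostics(sim, kernel)
  sim
}

#' Advance one semi-implicit IFEM step
#'
#' As [step_ifem()], but the interaction force carries only the internal
#' stress mismatch; inertia and gravity act through the effective density
#' `rho_bar = rho_f + (rho_s - rho_f) I` in the momentum equation, with the
#' indicator field recomputed from the current solid position before the
#' fluid solve.
#'
#' @param sim an `ifem_sim`.
#' @return the advanced simulation.
#' @export
step_semi_implicit <- function(sim) {
  kernel <- build_kernel(sim$em, sim$lm, sim$kernel_kind)
  sigma_s <- solid_stress(sim$lm, sim$mat, sim$solid)
  divf <- fluid_stress_divergence_at_solid(sim$em, sim$fluid, sim$props,
                                           kernel, sim$lm)
  f_s <- fsi_force_semi_implicit(sim$lm, sigma_s, divf,
                                 current = sim$mat$kind == "mooney-rivlin")
  f_f <- distribute_to_fluid(kernel, f_s)
  I <- solve_indicator(sim$em, sim$lm, sim$indicator_band)
  rho_bar <- effective_density(I, sim$props$rho, sim$mat$rho)
  fluid_new <- solve_fluid_step(sim$em, sim$fluid, sim$props, sim$dt,
                                sim$fluid_bcs, fsi_force = f_f,
                                rho_bar = rho_bar,
                                picard_max = sim$picard_max,
                                picard_tol = sim$picard_tol,
                                picard_fail = sim$picard_fail)
  vs <- interpolate_to_solid(kernel, fluid_new$v)
  sim$vs_prev <- sim$solid$v
  sim$solid$v <- vs
  old_cur <- sim$lm$cur
  sim$solid <- update_positions(sim$solid, sim$dt)
  cl <- clamp_into_domain(sim$em, old_cur, sim$lm$ref + sim$solid$u)
  if (length(cl$clamped))
    sim$solid$u[cl$clamped, ] <- cl$pts[cl$clamped, , drop = FALSE] -
      sim$lm$ref[cl$clamped, , drop = FALSE]
  sim$lm$cur <- sim$lm$ref + sim$solid$u
  sim$fluid_prev <- sim$fluid
  sim$fluid <- fluid_new
  sim$indicator <- I
  sim$f_fsi_s <- f_s; sim$f_fsi_f <- f_f
  sim$step <- sim$step + 1L
  sim <- check_cfl(sim)
  sim$history[[length(sim$history) + 1L]] <-
    sim_diagnostics(sim, kernel, clip_eps = attr(I, "clip_eps"))
  sim
}

# fluid traction on the solid boundary edges, interpolated from the fluid
# stress field (element stress projected to fluid nodes, then to solid
# boundary segment midpoints); returns a traction bc list for the solid
fluid_traction_on_solid <- function(sim, kernel) {
  sig <- fluid_stress(sim$em, sim$fluid, sim$props)
  n <- nrow(sim$em$nodes)
  tri <- sim$em$tri
  fd <- get_femdata(sim$em)
  lump <- get_lumped(sim$em)
  signod <- matrix(0, n, 3)
  for (a in 1:3) for (k in 1:3)
    signod[, k] <- signod[, k] + accum(tri[, a], fd$area / 3 * sig[, k], n)
  signod <- signod / lump
  bn <- boundary_normals(sim$lm)
  loc <- locate_points(sim$em, bn$mid)
  sigm <- matrix(0, nrow(bn$mid), 3)
  for (a in 1:3)
    sigm <- sigm + loc$bary[, a] * signod[tri[loc$elem, a], , drop = FALSE]
  # traction exerted by the fluid on the solid surface: sigma^f . n with n
  # the outward solid normal
  tx <- sigm[, 1] * bn$normal[, 1] + sigm[, 3] * bn$normal[, 2]
  ty <- sigm[, 3] * bn$normal[, 1] + sigm[, 2] * bn$normal[, 2]
  lapply(seq_along(bn$len), function(k) {
    list(edges = matrix(c(bn$n1[k], bn$n2[k]), 1, 2),
         value = c(tx[k], ty[k]))
  })
}

#' Advance one modified IFEM (mIFEM) step
#'
#' The solid momentum equation is *solved* (implicit Newmark) with boundary
#' data interpolated from the previous fluid state; the interaction force is
#' the internal mismatch plus the correction force; the fluid is solved with
#' the effective density and (optionally) pseudo-compressible continuity in
#' the overlap.  The solid velocity comes from its own dynamics and is never
#' overwritten by fluid interpolation.
#'
#' @param sim an `ifem_sim`.
#' @return the advanced simulation.
#' @export
step_mifem <- function(sim) {
  kernel0 <- build_kernel(sim$em, sim$lm, sim$kernel_kind)
  fixed <- sim$solid_bcs$fixed_nodes %||% integer(0)
  bcs_solid <- list(dirichlet = list(), traction = list())
  if (length(fixed))
    bcs_solid$dirichlet <- list(list(nodes = fixed))
  if (identical(sim$solid_bcs$fsi %||% "traction", "traction")) {
    bcs_solid$traction <- fluid_traction_on_solid(sim, kernel0)
  } else {
    vb <- interpolate_to_solid(kernel0, sim$fluid$v)
    bnodes <- setdiff(unique(unlist(sim$lm$loops %||% list(sim$lm$boundary))),
                      fixed)
    utarget <- sim$solid$u[bnodes, , drop = FALSE] +
      vb[bnodes, , drop = FALSE] * sim$dt
    bcs_solid$dirichlet <- c(bcs_solid$dirichlet,
                             list(list(nodes = bnodes, value = utarget)))
  }
  solid_new <- solve_solid_dynamics(sim$lm, sim$solid, sim$mat, bcs_solid,
                                    sim$dt)
  lm_new <- sim$lm
  lm_new$cur <- lm_new$ref + solid_new$u
  kernel <- build_kernel(sim$em, lm_new, sim$kernel_kind)
  sigma_s <- solid_stress(lm_new, sim$mat, solid_new)
  divf <- fluid_stress_divergence_at_solid(sim$em, sim$fluid, sim$props,
                                           kernel, lm_new)
  dvs_dt <- (solid_new$v - sim$solid$v) / sim$dt
  ms <- lumped_areas(lm_new$ref, lm_new$tri)
  corr_mass <- corr_load <- NULL
  f_dv_rhs <- matrix(0, nrow(sim$lm$ref), 2)
  if (sim$correction) {
    # f_dv = rho_s (Dv^s/Dt - Dv^f/Dt): the solid part is a distributed
    # load, the fluid material derivative is discretized implicitly inside
    # the fluid solve (corr_mass), which stabilizes the staggered coupling
    f_dv_rhs <- cbind(sim$mat$rho * ms * dvs_dt[, 1],
                      sim$mat$rho * ms * dvs_dt[, 2])
    corr_mass <- distribute_to_fluid(kernel, sim$mat$rho * ms)
    corr_load <- distribute_to_fluid(kernel, f_dv_rhs)
  }
  f_s <- fsi_force_semi_implicit(lm_new, sigma_s, divf) + f_dv_rhs
  f_f <- distribute_to_fluid(kernel,
                             fsi_force_semi_implicit(lm_new, sigma_s, divf))
  I <- solve_indicator(sim$em, lm_new, sim$indicator_band)
  rho_bar <- effective_density(I, sim$props$rho, sim$mat$rho)
  fluid_new <- solve_fluid_step(
    sim$em, sim$fluid, sim$props, sim$dt, sim$fluid_bcs,
    fsi_force = f_f, rho_bar = rho_bar,
    mode = if (sim$pseudo_compressible) "pseudo-compressible" else
      "incompressible",
    kappa = sim$mat$kappa, indicator = I,
    corr_mass = corr_mass, corr_load = corr_load,
    picard_max = sim$picard_max, picard_tol = sim$picard_tol,
    picard_fail = sim$picard_fail)
  f_f <- f_f + (if (sim$correction) corr_load else 0)
  noslip <- sqrt(mean((interpolate_to_solid(kernel, fluid_new$v) -
                         solid_new$v)^2))
  sim$vs_prev <- sim$solid$v
  sim$solid <- solid_new
  sim$lm <- lm_new
  sim$fluid_prev <- sim$fluid
  sim$fluid <- fluid_new
  sim$indicator <- I
  sim$f_fsi_s <- f_s; sim$f_fsi_f <- f_f
  sim$step <- sim$step + 1L
  sim <- check_cfl(sim)
  sim$history[[length(sim$history) + 1L]] <-
    sim_diagnostics(sim, kernel, clip_eps = attr(I, "clip_eps"),
                    noslip = noslip)
  sim
}

#' Advance one step with the configured algorithm
#' @param sim an `ifem_sim`.
#' @export
step_sim <- function(sim) {
  switch(sim$algorithm,
         ifem = step_ifem(sim),
         semi_implicit = step_semi_implicit(sim),
         mifem = step_mifem(sim))
}

#' Run a simulation for several steps
#'
#' @param sim an `ifem_sim`.
#' @param n_steps number of steps.
#' @param out_dir if given, VTU states are written there every
#'   `cadence` steps (plus the final step).
#' @param cadence output cadence (steps).
#' @return the advanced simulation; retrieve per-step diagnostics with
#'   [sim_history()].
#' @export
run_sim <- function(sim, n_steps, out_dir = NULL, cadence = 10L) {
  for (k in seq_len(n_steps)) {
    sim <- step_sim(sim)
    if (!is.null(out_dir) && (sim$step %% cadence == 0L || k == n_steps))
      write_state(out_dir, sim$step, sim)
  }
  sim
}

#' Per-step diagnostics of a simulation
#' @param sim an `ifem_sim`.
#' @return data.frame with one row per completed step (divergence norm,
#'   force-conservation residual, CFL number, solid centroid, ...).
#' @export
sim_history <- function(sim) {
  do.call(rbind, sim$history)
}
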
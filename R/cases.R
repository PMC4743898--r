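# Reproducible demo cases at desk scale: a deformable cell entering a
# bifurcated microvessel (explicit IFEM) and a mirrored pair of two-layer
# elastic folds in a pressure-driven air channel (mIFEM), plus the
# diagnostics they report (branch selection, glottis half-widths, volume
# flow rate, power spectra).

#' Merge several solid meshes into one multi-body Lagrangian mesh
#'
#' Node indices are offset and boundary loops kept per body; layer labels
#' and `fixed_nodes` attributes are concatenated.
#' @param lms list of `lagrangian_mesh` objects.
#' @export
merge_lagrangian_meshes <- function(lms) {
  off <- 0L
  ref <- NULL; tri <- NULL; loops <- list(); layer <- NULL
  fixed <- integer(0)
  for (lm in lms) {
    ref <- rbind(ref, lm$ref)
    tri <- rbind(tri, lm$tri + off)
    loops <- c(loops, lapply(lm$loops %||% list(lm$boundary),
                             function(lp) lp + off))
    layer <- c(layer, lm$layer)
    fx <- attr(lm, "fixed_nodes")
    if (!is.null(fx)) fixed <- c(fixed, fx + off)
    off <- off + nrow(lm$ref)
  }
  out <- lagrangian_mesh(ref, tri, boundary = loops, layer = layer)
  attr(out, "fixed_nodes") <- fixed
  out
}

#' Cell-in-bifurcation demo case (explicit IFEM)
#'
#' One soft disc (default radius 2.66 um, a red-blood-cell scale) released
#' on the mother-vessel axis of a w0 = 8 um bifurcation, advected by a
#' steady perfusion with mean inlet speed 0.1 cm/s and a prescribed outlet
#' flow split `Q1/Q2`.  The run stops once the cell centroid passes the
#' bifurcation apex by one cell radius (or after `n_steps`).
#'
#' @param r_d diameter ratio w1/w2 of the daughter branches.
#' @param flow_ratio Q1/Q2 flow split between the upper and lower branch.
#' @param n_steps maximum number of time steps.
#' @param dt time step (s).
#' @param h fluid element size (um).
#' @param cell_radius cell radius (um).
#' @param release release position of the cell centre (um, mother-vessel
#'   frame with the junction near x = 0); default on the axis.
#' @param inlet_mean mean inlet velocity (cm/s).
#' @param E_cell,nu_cell,eta_cell,rho_cell cell material (dyn/cm^2 etc.).
#' @param mu,rho_f plasma viscosity (g/cm/s) and density (g/cm^3).
#' @param cell_kind material kind of the cell ([material_model()]).
#' @param cell_refine number of element rings across the cell radius.
#' @return list of class `bifurcation_diagnostics`: `branch` (1 = upper,
#'   2 = lower, 0 = undecided), `history` (per-step diagnostics incl. the
#'   centroid trajectory in cm), `apex_x` (cm), and the configuration.
#' @export
rbc_bifurcation_case <- function(r_d = 1, flow_ratio = 1, n_steps = 1800L,
                                 dt = 2e-5, h = 0.85, cell_radius = 2.66,
                                 release = c(-7, 0), inlet_mean = 0.1,
                                 E_cell = 200, nu_cell = 0.45,
                                 eta_cell = 0.02, rho_cell = 1.1,
                                 mu = 0.012, rho_f = 1.03,
                                 cell_kind = "viscoelastic",
                                 cell_refine = 4) {
  geom <- bifurcation_geometry(w0 = 8, r_d = r_d, h = h)
  em <- with_femdata(generate_bifurcation_mesh(geom))
  od <- attr(em, "outlet_dirs")
  apex_x <- attr(em, "apex_x")
  lm <- generate_disc_mesh(um(release), um(cell_radius),
                           um(cell_radius) / cell_refine)
  props <- fluid_properties(rho_f, mu)
  mat <- material_model(cell_kind, E = E_cell, nu = nu_cell,
                        rho = rho_cell, eta = eta_cell, strain_cap = 0.5)
  w0 <- um(geom$w0)
  # parabolic inlet profile with the requested mean
  inlet_fun <- function(x, y) {
    cbind(1.5 * inlet_mean * (1 - (2 * y / w0)^2), 0 * y)
  }
  # discrete inlet flux (trapezoid over boundary nodes), split Q1:Q2
  iy <- sort(em$nodes[em$tags$inlet, 2])
  uin <- 1.5 * inlet_mean * (1 - (2 * iy / w0)^2)
  Q0 <- sum(diff(iy) * (head(uin, -1) + tail(uin, -1)) / 2)
  Q1 <- Q0 * flow_ratio / (1 + flow_ratio)
  Q2 <- Q0 / (1 + flow_ratio)
  out_fun <- function(which) {
    dir <- if (which == 1L) od$outlet1 else od$outlet2
    nv <- if (which == 1L) od$n1v else od$n2v
    endc <- if (which == 1L) od$end1 else od$end2
    w <- if (which == 1L) od$w1 else od$w2
    Q <- if (which == 1L) Q1 else Q2
    vmax <- 1.5 * Q / w
    function(x, y) {
      s <- (x - endc[1]) * nv[1] + (y - endc[2]) * nv[2]
      prof <- vmax * pmax(0, 1 - (2 * s / w)^2)
      cbind(prof * dir[1], prof * dir[2])
    }
  }
  bcs <- list(list(tag = "wall", type = "noslip"),
              list(tag = "inlet", type = "dirichlet", value = inlet_fun),
              list(tag = "outlet1", type = "dirichlet", value = out_fun(1L)),
              list(tag = "outlet2", type = "dirichlet", value = out_fun(2L)))
  sim <- ifem_sim(em, lm, props, mat, dt = dt, fluid_bcs = bcs,
                  algorithm = "ifem", cfl_warn = 2)
  # establish the perfusion before releasing the cell: a steady solve of the
  # pure fluid problem replaces the impulsive start-up transient
  sim$fluid <- solve_fluid_step(em, sim$fluid, props, dt = Inf, bcs = bcs)
  # stop shortly after the centroid passes the apex nose: the branch choice
  # is decided there, and a linear small-strain cell squeezed deep into a
  # daughter narrower than itself would leave the model's validity range
  stop_x <- apex_x + um(0.5)
  aborted <- NA_character_
  for (k in seq_len(n_steps)) {
    sim2 <- tryCatch(step_sim(sim), error = function(e) e)
    if (inherits(sim2, "error")) { aborted <- conditionMessage(sim2); break }
    sim <- sim2
    if (tail(sim$history, 1)[[1]]$centroid_x > stop_x) break
  }
  hist <- sim_history(sim)
  # branch label: sign of the transverse centroid coordinate once the
  # centroid has passed the apex nose (1 = upper daughter, 2 = lower)
  past <- hist$centroid_x > apex_x
  branch <- if (!any(past)) 0L
  else if (hist$centroid_y[max(which(past))] > 0) 1L else 2L
  structure(list(branch = branch, history = hist, apex_x = apex_x,
                 Q1 = Q1, Q2 = Q2, geom = geom, sim = sim,
                 aborted = aborted),
            class = "bifurcation_diagnostics")
}

#' Half glottis widths of a fold pair
#'
#' Minimum distance between each fold surface and the channel centerline,
#' clamped at zero (zero means the fold touches the centerline: the
#' glottis is closed).
#'
#' @param lm_up,lm_down fold meshes (current configuration).
#' @param centerline_y y-coordinate of the channel centerline (cm).
#' @return named numeric: `Gw_up`, `Gw_down` (cm).
#' @export
glottis_width <- function(lm_up, lm_down, centerline_y) {
  yd <- lm_down$cur[unique(unlist(lm_down$loops %||%
                                    list(lm_down$boundary))), 2]
  yu <- lm_up$cur[unique(unlist(lm_up$loops %||% list(lm_up$boundary))), 2]
  c(Gw_up = max(0, min(yu) - centerline_y),
    Gw_down = max(0, centerline_y - max(yd)))
}

# interpolated volume flow rate (per unit depth) through a vertical section
section_flow_rate <- function(em, state, x_s, y_range, n = 41L) {
  ys <- seq(y_range[1], y_range[2], length.out = n)
  pts <- cbind(rep(x_s, n), ys)
  loc <- locate_points(em, pts)
  ux <- numeric(n)
  for (a in 1:3)
    ux <- ux + loc$bary[, a] * state$v[em$tri[cbind(loc$elem, a)], 1]
  sum(diff(ys) * (head(ux, -1) + tail(ux, -1)) / 2)
}

#' Self-oscillating two-layer fold demo case (mIFEM)
#'
#' Two mirrored two-layer elastic bodies attached to the walls of a
#' pressure-driven air channel: cover layer E = 10 kPa, body layer
#' E = 40 kPa, rho_s = 1 g/cm^3, nu = 0.3, air with rho_f = 1.3e-3 g/cm^3
#' and mu = 1.8e-4 g/(cm s), constant total pressure at the inlet and
#' outflow at the exit (solid/fluid density ratio about 770).  `scale`
#' multiplies the inlet pressure: 1 is the full 1 kPa drive, smaller values
#' give slower, cheaper runs.
#'
#' @param scale inlet-pressure scale factor (P_in = scale * 1 kPa).
#' @param n_steps number of time steps.
#' @param dt time step (s).
#' @param h fluid element size (cm).
#' @param channel_len,channel_height channel dimensions (cm).
#' @param eta_s solid Kelvin-Voigt viscosity (dyn s/cm^2).
#' @param out_dir optional VTU output directory.
#' @return list of class `fold_diagnostics`: data.frame `series` with time,
#'   `Gw_up`, `Gw_down` (cm) and flow rate `Q` (cm^2/s), the final
#'   simulation, and the configuration.
#' @export
flapping_fold_case <- function(scale = 0.02, n_steps = 60L, dt = 1e-5,
                               h = 1 / 13, channel_len = 2.0,
                               channel_height = 1.0, eta_s = 2,
                               out_dir = NULL) {
  em <- with_femdata(generate_channel_mesh(channel_len, channel_height, h))
  folds <- generate_two_layer_fold_mesh(base_x0 = 0.55, length = 0.35,
                                        height = 0.42, taper = 0.3,
                                        cover_frac = 0.35,
                                        channel_height = channel_height,
                                        h = 0.045)
  lm <- merge_lagrangian_meshes(list(folds$down, folds$up))
  # layered material: the base material is the soft cover (E = 10 kPa), the
  # body layer is stiffened element-wise by E_body / E_cover = 4
  lm$stiffness_scale <- ifelse(lm$layer == "cover", 1, 4)
  mat_cover <- material_model("viscoelastic", E = 1e4, nu = 0.3, rho = 1.0,
                              eta = eta_s)
  Pin <- 1e4 * scale
  ramp_t <- 10 * dt
  bcs <- list(list(tag = "wall", type = "noslip"),
              list(tag = "inlet", type = "traction", pressure = Pin),
              list(tag = "outlet", type = "outflow"))
  sim <- ifem_sim(em, lm, fluid_properties(1.3e-3, 1.8e-4), mat_cover,
                  dt = dt, fluid_bcs = bcs, algorithm = "mifem",
                  solid_bcs = list(fixed_nodes = attr(lm, "fixed_nodes"),
                                   fsi = "traction"),
                  cfl_warn = 10, picard_max = 40)
  yc <- channel_height / 2
  nd <- nrow(folds$down$ref)
  series <- vector("list", n_steps)
  glottis_x <- 0.55 + 0.35 / 2
  for (k in seq_len(n_steps)) {
    sim <- step_sim(sim)
    lm_d <- folds$down; lm_d$cur <- sim$lm$cur[seq_len(nd), , drop = FALSE]
    lm_u <- folds$up
    lm_u$cur <- sim$lm$cur[nd + seq_len(nrow(folds$up$ref)), , drop = FALSE]
    gw <- glottis_width(lm_u, lm_d, yc)
    Q <- section_flow_rate(sim$em, sim$fluid, glottis_x,
                           c(0, channel_height))
    series[[k]] <- data.frame(t = sim$fluid$t, Gw_up = gw["Gw_up"],
                              Gw_down = gw["Gw_down"], Q = Q)
    if (!is.null(out_dir) && k %% 10L == 0L) write_state(out_dir, k, sim)
  }
  structure(list(series = do.call(rbind, series), sim = sim,
                 Pin = Pin, density_ratio = 1.0 / 1.3e-3),
            class = "fold_diagnostics")
}

#' Dominant frequency of a scalar time series
#'
#' Peak of the one-sided power spectrum, excluding the zero-frequency bin.
#' A constant series has no peak and returns `NA` with a flag.
#'
#' @param series numeric vector, uniformly sampled.
#' @param dt sampling interval (s).
#' @return list with `freq_hz` (peak frequency), `power` (spectrum),
#'   `freqs` (frequency axis, Hz) and `flat` (TRUE when no peak exists).
#' @export
spectrum <- function(series, dt) {
  n <- length(series)
  x <- series - mean(series)
  if (max(abs(x)) < 1e-14 * max(1, max(abs(series)))) {
    return(list(freq_hz = NA_real_, power = NULL, freqs = NULL, flat = TRUE))
  }
  p <- Mod(stats::fft(x))^2 / n
  nf <- floor(n / 2)
  freqs <- (seq_len(nf)) / (n * dt)   # excludes the zero bin
  power <- p[2:(nf + 1)]
  list(freq_hz = freqs[which.max(power)], power = power, freqs = freqs,
       flat = FALSE)
}
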
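#' Fluid properties for the blood analogue
#'
#' Blood is treated as an incompressible Newtonian fluid with rigid walls.
#' The defaults (dynamic viscosity 3.5 mPa s, density 1056 kg/m^3) are the
#' conventional values for blood-analogue coronary simulations and are
#' freely configurable.
#'
#' @param dynamic_viscosity Dynamic viscosity (Pa s), > 0.
#' @param density Density (kg/m^3), > 0.
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(dynamic_viscosity = 3.5e-3, density = 1056) {
  if (dynamic_viscosity <= 0 || density <= 0)
    .stopf("fluid_properties: viscosity and density must be > 0")
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_properties")
}

#' Boundary conditions for the characterization protocol
#'
#' The lesion characterization protocol fixes a plug (spatially uniform)
#' inlet velocity delivering `inlet_flow` mL/s, a uniform zero gauge
#' pressure at the outlet, and no-slip rigid walls.
#'
#' @param inlet_flow Volumetric inlet flow (mL/s), > 0.
#' @param outlet_pressure Outlet gauge pressure (Pa); the characterization
#'   protocol uses 0.
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(inlet_flow, outlet_pressure = 0) {
  if (inlet_flow <= 0)
    .stopf("boundary_conditions: inlet_flow must be > 0 (got %s)",
           format(inlet_flow))
  structure(list(inlet_flow = inlet_flow, inlet_profile = "plug",
                 outlet_pressure = outlet_pressure, wall = "no-slip"),
            class = "boundary_conditions")
}

#' Solver controls
#'
#' SIMPLE-type pressure-based coupling with second-order upwind convection
#' and central diffusion. Convergence is declared when the normalized
#' momentum and continuity residuals all drop below `tol`.
#'
#' @param alpha_u,alpha_p Momentum / pressure under-relaxation factors.
#' @param tol Normalized residual tolerance.
#' @param max_outer Outer (SIMPLE) iteration cap.
#' @param second_order Use the deferred second-order upwind convection
#'   correction (default `TRUE`).
#' @param re_laminar_cap Reynolds number above which a laminar-assumption
#'   warning is recorded in the solution metadata.
#' @param n_stations Minimum number of arclength stations for the
#'   cross-section-averaged pressure.
#' @return A `solver_controls` object.
#' @export
solver_controls <- function(alpha_u = 0.5, alpha_p = 0.2, tol = 1e-5,
                            max_outer = 4000, second_order = TRUE,
                            re_laminar_cap = 2000, n_stations = 64) {
  structure(list(alpha_u = alpha_u, alpha_p = alpha_p, tol = tol,
                 max_outer = as.integer(max_outer),
                 second_order = isTRUE(second_order),
                 re_laminar_cap = re_laminar_cap,
                 n_stations = as.integer(n_stations)),
            class = "solver_controls")
}

#' Solve steady incompressible flow on a tube mesh
#'
#' Discretizes the incompressible Navier-Stokes equations with the finite
#' volume method and solves them with a pressure-based (SIMPLE) scheme to
#' steady state, assuming laminar flow. Returns the converged fields
#' together with the cross-section-averaged pressure along the vessel,
#' the residual history and the wall-clock duration (meshing time is not
#' included, matching the benchmarking convention).
#'
#' @param mesh A `tube_mesh` from [build_mesh()].
#' @param fluid A [fluid_properties()].
#' @param bc A [boundary_conditions()].
#' @param controls A [solver_controls()].
#' @return A `flow_solution` with per-cell `velocity` (m/s) and `pressure`
#'   (Pa), `residual_history`, `converged`, `section_pressure` (data.frame:
#'   arclength mm, pressure Pa), `duration_s`, `flux_imbalance_rel`,
#'   `reynolds` and any `warnings`.
#' @export
solve_steady <- function(mesh, fluid = fluid_properties(),
                         bc = boundary_conditions(1),
                         controls = solver_controls()) {
  stopifnot(inherits(mesh, "tube_mesh"))
  q_si <- bc$inlet_flow * M3S_PER_MLS

  inlet_faces <- which(mesh$btype == 1L)
  a_inlet <- sum(.row_norms(mesh$Sf[inlet_faces, , drop = FALSE]))
  u_plug <- q_si / a_inlet
  # plug velocity along the inward normal of each inlet face
  uin <- matrix(0, nrow = nrow(mesh$Sf), ncol = 3)
  nrm <- mesh$Sf[inlet_faces, , drop = FALSE] /
    .row_norms(mesh$Sf[inlet_faces, , drop = FALSE])
  uin[inlet_faces, ] <- -u_plug * nrm

  # mass-consistent initial guess: local mean axial velocity along the tube
  geom <- mesh$geometry
  s_mm <- mesh$layer_arclength_mm
  if (!is.null(geom$spec)) {
    r_mm <- .spec_radius(geom$spec, s_mm)
    tng <- .spec_frame(geom$spec, s_mm)$tangent
  } else {
    r_mm <- spline(geom$arclength, geom$radius_profile, xout = s_mm)$y
    tng <- apply(geom$tangent, 2, function(col)
      approx(geom$arclength, col, xout = s_mm)$y)
    tng <- tng / .row_norms(tng)
  }
  u_mean <- q_si / (pi * (r_mm * M_PER_MM)^2)
  u0 <- u_mean[mesh$cell_layer] * tng[mesh$cell_layer, , drop = FALSE]

  t0 <- proc.time()[["elapsed"]]
  raw <- .fv_simple_solve(
    owner_ = mesh$owner - 1L,
    neigh_ = ifelse(is.na(mesh$neigh), -1L, mesh$neigh - 1L),
    btype_ = mesh$btype, Sf_ = mesh$Sf, Cf_ = mesh$Cf,
    Cc_ = mesh$cell_centroid, vol_ = mesh$cell_volume, uin_ = uin,
    u0_ = u0, mu = fluid$dynamic_viscosity, rho = fluid$density,
    alpha_u = controls$alpha_u, alpha_p = controls$alpha_p,
    tol = controls$tol, max_outer = controls$max_outer, min_outer = 5L,
    second_order = controls$second_order)
  duration <- proc.time()[["elapsed"]] - t0

  if (!raw$converged) {
    cond <- structure(class = c("vffrsim_divergence", "error", "condition"),
                      list(message = sprintf(
                        paste0("solve_steady: not converged after %d outer ",
                               "iterations (final residuals %s)"),
                        raw$iterations,
                        paste(signif(tail(raw$residuals, 1), 3),
                              collapse = ", ")),
                        call = sys.call(),
                        residual_history = raw$residuals))
    stop(cond)
  }

  # cross-section-averaged pressure: volume-weighted layer means,
  # interpolated onto >= n_stations stations including the inlet plane
  layer_p <- as.vector(
    rowsum(raw$p * mesh$cell_volume, mesh$cell_layer) /
      rowsum(mesh$cell_volume, mesh$cell_layer))
  L <- geom$arclength_total
  n_st <- max(controls$n_stations, mesh$nx + 1L)
  st <- seq(0, L, length.out = n_st)
  sp <- approx(c(0, s_mm, L), c(
    layer_p[1] + (layer_p[1] - layer_p[2]) * (s_mm[1] / (s_mm[2] - s_mm[1])),
    layer_p,
    layer_p[mesh$nx] - (layer_p[mesh$nx - 1L] - layer_p[mesh$nx]) *
      (s_mm[1] / (s_mm[2] - s_mm[1]))), xout = st)$y

  r_min_m <- min(r_mm) * M_PER_MM
  reynolds <- 2 * fluid$density * q_si / (pi * r_min_m * fluid$dynamic_viscosity)
  warn <- character(0)
  if (reynolds > controls$re_laminar_cap)
    warn <- sprintf(
      "throat Reynolds number %.0f exceeds the laminar cap %.0f; laminar model retained",
      reynolds, controls$re_laminar_cap)

  if (isTRUE(raw$quasi_steady))
    warn <- c(warn, sprintf(
      paste0("self-excited flow oscillation: solution is the cycle mean ",
             "(residual band 1e-2, cycle-mean drift %.2e)"),
      raw$cycle_mean_drift))
  structure(list(
    velocity = raw$u, pressure = raw$p, face_flux = raw$phi,
    residual_history = raw$residuals, converged = raw$converged,
    convergence_mode = if (isTRUE(raw$quasi_steady))
      "quasi_steady_cycle_mean" else "steady",
    iterations = raw$iterations,
    section_pressure = data.frame(arclength = st, pressure = sp),
    duration_s = duration,
    mass_flux_in = raw$mass_flux_in, mass_flux_out = raw$mass_flux_out,
    flux_imbalance_rel = raw$flux_imbalance_rel,
    reynolds = reynolds, warnings = warn,
    inlet_flow = bc$inlet_flow, fluid = fluid,
    n_cells = mesh$cell_count,
    fidelity_percent = if (inherits(mesh$fidelity, "fidelity_level"))
      mesh$fidelity$percent else NA_integer_
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> Q %.2f mL/s on %d cells: %s in %d iterations (%.2f s)\n",
    x$inlet_flow, x$n_cells,
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$duration_s))
  cat(sprintf("  inlet->outlet pressure drop %.1f Pa, Re %.0f, flux imbalance %.1e\n",
              x$section_pressure$pressure[1] -
                tail(x$section_pressure$pressure, 1),
              x$reynolds, x$flux_imbalance_rel))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Translesional pressure drop between two arclength stations
#'
#' `section_pressure(s_proximal) - section_pressure(s_distal)`; this may be
#' negative downstream of a throat where pressure partially recovers.
#'
#' @param solution A `flow_solution`.
#' @param s_proximal,s_distal Arclength positions (mm),
#'   `s_proximal < s_distal`, both inside the vessel.
#' @return Pressure drop in Pa.
#' @export
pressure_drop <- function(solution, s_proximal, s_distal) {
  sp <- solution$section_pressure
  rng <- range(sp$arclength)
  if (s_proximal < rng[1] || s_distal > rng[2] || s_proximal > s_distal)
    .stopf("pressure_drop: stations [%s, %s] mm outside the solved domain [%s, %s] mm",
           format(s_proximal), format(s_distal),
           format(rng[1]), format(rng[2]))
  pr <- approx(sp$arclength, sp$pressure, xout = c(s_proximal, s_distal))$y
  pr[1] - pr[2]
}

#' Hagen-Poiseuille pressure drop oracle
#'
#' Exact fully developed laminar pressure drop in a straight circular tube,
#' `8 mu L Q / (pi R^4)`, used as an analytic validation reference for the
#' finite-volume solver.
#'
#' @param radius Tube radius (m).
#' @param length Tube length (m).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param flow Volumetric flow (m^3/s).
#' @return Pressure drop in Pa.
#' @examples
#' poiseuille_dp(1.5e-3, 30e-3, 3.5e-3, 1e-6)  # ~52.8 Pa
#' @export
poiseuille_dp <- function(radius, length, viscosity, flow) {
  stopifnot(radius > 0, length > 0, viscosity > 0, flow > 0)
  8 * viscosity * length * flow / (pi * radius^4)
}

#' Empirical viscous-plus-inertial stenosis pressure-drop estimate
#'
#' Order-of-magnitude reference in the classical viscous + inertial
#' (Young-Tsai family) form
#' `dP = K_v * mu * U / D0 * (A0/At)^2 + K_t * rho/2 * (A0/At - 1)^2 * U^2`,
#' with U the reference-segment mean velocity. Used for sanity bounds on
#' solved stenosed cases, not for equality checks.
#'
#' @param reference_diameter Reference lumen diameter (m).
#' @param stenosis_pct Percent diameter stenosis.
#' @param fluid A [fluid_properties()].
#' @param flow Volumetric flow (m^3/s).
#' @param K_v,K_t Empirical viscous / turbulent-expansion constants.
#' @return List with `viscous_pa`, `inertial_pa` and `total_pa`.
#' @export
stenosis_dp_estimate <- function(reference_diameter, stenosis_pct,
                                 fluid = fluid_properties(), flow,
                                 K_v = 32, K_t = 1.52) {
  stopifnot(reference_diameter > 0, flow > 0)
  a_ratio <- 1 / (1 - stenosis_pct / 100)^2  # A0 / At
  area0 <- pi * reference_diameter^2 / 4
  u0 <- flow / area0
  viscous <- K_v * fluid$dynamic_viscosity * u0 / reference_diameter * a_ratio^2
  inertial <- K_t * fluid$density / 2 * (a_ratio - 1)^2 * u0^2
  list(viscous_pa = viscous, inertial_pa = inertial,
       total_pa = viscous + inertial,
       constants = c(K_v = K_v, K_t = K_t))
}
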
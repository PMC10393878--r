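#' Fit the two-point quadratic pressure-flow characteristic
#'
#' Two steady simulations at distinct flows characterize a lesion by
#' `dP(Q) = f Q + s Q^2`: `f` is the linear (viscous) term, `s` the
#' quadratic (inertial) term. The 2x2 system through the two points is
#' solved exactly, so the fitted curve reproduces both inputs to machine
#' precision. A negative fitted `f` or `s` (possible from discretization
#' noise on nearly unobstructed vessels) is flagged, not fatal.
#'
#' @param q1,q2 Characterization flows (mL/s), distinct and > 0. The
#'   benchmark protocol uses 1 and 3 mL/s.
#' @param dp1,dp2 Corresponding translesional pressure drops (mmHg).
#' @param measurement_arclength Optional arclength (mm) of the distal
#'   measurement point the drops refer to.
#' @return A `pressure_flow_curve` with fields `f` (mmHg/(mL/s)) and
#'   `s` (mmHg/(mL/s)^2).
#' @examples
#' fit_pressure_flow(1, 10, 3, 42)  # f = 8, s = 2
#' @export
fit_pressure_flow <- function(q1, dp1, q2, dp2,
                              measurement_arclength = NA_real_) {
  if (q1 <= 0 || q2 <= 0)
    .stopf("fit_pressure_flow: flows must be > 0")
  if (q1 == q2)
    .stopf("fit_pressure_flow: singular system, q1 == q2 == %s", format(q1))
  # dp = f q + s q^2 through both points, eliminated directly
  s <- (dp2 / q2 - dp1 / q1) / (q2 - q1)
  f <- dp1 / q1 - s * q1
  structure(list(f = f, s = s, q_points = c(q1, q2), dp_points = c(dp1, dp2),
                 measurement_arclength = measurement_arclength,
                 nonphysical = (f < 0 || s < 0)),
            class = "pressure_flow_curve")
}

#' @export
print.pressure_flow_curve <- function(x, ...) {
  cat(sprintf(
    "<pressure_flow_curve> dP(Q) = %.4g Q + %.4g Q^2  [mmHg, mL/s]%s\n",
    x$f, x$s, if (x$nonphysical) "  (flagged: negative coefficient)" else ""))
  invisible(x)
}

#' Predict the pressure drop of a fitted characteristic
#' @param curve A `pressure_flow_curve`.
#' @param q Flow (mL/s).
#' @return Pressure drop (mmHg).
#' @export
predict_dp <- function(curve, q) curve$f * q + curve$s * q^2

# positive operating-point flow of s Q^2 + (f + R) Q - Pa = 0
.operating_flow <- function(f, s, Pa, R_mv) {
  b <- f + R_mv
  if (abs(s) < 1e-12 * max(1, abs(b))) {
    q <- Pa / b
  } else {
    disc <- b^2 + 4 * s * Pa
    if (disc < 0)
      .stopf("vffr: no real operating point (f=%g, s=%g, Pa=%g, R_mv=%g)",
             f, s, Pa, R_mv)
    roots <- c((-b + sqrt(disc)) / (2 * s), (-b - sqrt(disc)) / (2 * s))
    pos <- roots[roots > 0]
    if (!length(pos))
      .stopf("vffr: no positive operating flow (f=%g, s=%g, Pa=%g, R_mv=%g)",
             f, s, Pa, R_mv)
    q <- min(pos)
  }
  q
}

#' Closed-form virtual fractional flow reserve
#'
#' Couples the lesion characteristic `dP(Q) = f Q + s Q^2` to a proximal
#' (aortic) pressure `Pa` and a lumped distal microvascular resistance
#' `R_mv` (`Pd = R_mv Q`), and solves the operating point algebraically:
#' the hyperaemic flow is the positive root of
#' `s Q^2 + (f + R_mv) Q - Pa = 0`, `Pd = R_mv Q`, `vFFR = Pd / Pa`.
#'
#' @param curve A [fit_pressure_flow()] result.
#' @param Pa Proximal pressure (mmHg), > 0. Default 100 mmHg.
#' @param R_mv Microvascular resistance (mmHg per mL/s), > 0. Default 25.
#' @return A `vffr_result` with fields `Pa`, `Pd`, `Q`, `vffr`, `method`.
#' @examples
#' compute_vffr_closed_form(fit_pressure_flow(1, 10, 3, 42), 100, 25)
#' @export
compute_vffr_closed_form <- function(curve, Pa = 100, R_mv = 25) {
  if (Pa <= 0 || R_mv <= 0)
    .stopf("vffr: Pa and R_mv must be > 0")
  q <- .operating_flow(curve$f, curve$s, Pa, R_mv)
  pd <- R_mv * q
  structure(list(Pa = Pa, Pd = pd, Q = q, vffr = pd / Pa,
                 method = "closed_form", iterations = NA_integer_,
                 curve = curve, R_mv = R_mv),
            class = "vffr_result")
}

#' Pseudo-transient virtual fractional flow reserve
#'
#' Solves the same coupled operating point as
#' [compute_vffr_closed_form()] by relaxed fixed-point iteration
#' `Q <- (1 - omega) Q + omega (Pa - f Q - s Q^2) / R_mv`, emulating a
#' pseudo-transient march to the steady operating point. The fixed point is
#' independent of the relaxation factor; the two methods are required to
#' agree to high precision, which is the correctness contract for the
#' coupling.
#'
#' @inheritParams compute_vffr_closed_form
#' @param relaxation Relaxation factor `omega` in (0, 1].
#' @param tol Convergence tolerance on `|dQ|` (mL/s).
#' @param max_iter Iteration cap.
#' @return A `vffr_result` (`method = "pseudo_transient"`, with
#'   `iterations`).
#' @export
compute_vffr_pseudo_transient <- function(curve, Pa = 100, R_mv = 25,
                                          relaxation = 0.5, tol = 1e-12,
                                          max_iter = 10000) {
  if (Pa <= 0 || R_mv <= 0)
    .stopf("vffr: Pa and R_mv must be > 0")
  if (relaxation <= 0 || relaxation > 1)
    .stopf("vffr: relaxation must lie in (0, 1]")
  if (tol <= 0) .stopf("vffr: tol must be > 0")
  f <- curve$f; s <- curve$s
  q0 <- Pa / (f + s + R_mv)  # cheap positive start
  q <- q0
  trace <- numeric(0)
  omega <- relaxation
  dq_prev <- Inf
  for (it in seq_len(max_iter)) {
    q_new <- (1 - omega) * q + omega * (Pa - f * q - s * q^2) / R_mv
    dq <- abs(q_new - q)
    # pseudo-time-step control (the fixed point itself is unchanged):
    # a growing or non-finite update means the map is unstable at this
    # relaxation -- restart from the initial point with a damped step;
    # a stalled update (|dq| not shrinking, e.g. exactly at the marginal
    # stability boundary) is damped in place
    if (!is.finite(dq) || (dq > dq_prev && omega > 1e-6)) {
      omega <- omega / 2
      q <- q0
      dq_prev <- Inf
      next
    }
    if (dq >= 0.995 * dq_prev && dq > tol && omega > 1e-6) {
      omega <- omega / 2
      dq_prev <- Inf
      next
    }
    dq_prev <- dq
    q <- q_new
    if (it <= 50L) trace <- c(trace, q)
    if (dq < tol) {
      pd <- R_mv * q
      return(structure(list(Pa = Pa, Pd = pd, Q = q, vffr = pd / Pa,
                            method = "pseudo_transient", iterations = it,
                            curve = curve, R_mv = R_mv),
                       class = "vffr_result"))
    }
  }
  cond <- structure(class = c("vffrsim_nonconvergence", "error", "condition"),
                    list(message = sprintf(
                      "pseudo-transient vffr did not converge in %d iterations (|dQ| trace attached)",
                      max_iter), call = sys.call(), trace = trace))
  stop(cond)
}

#' @export
print.vffr_result <- function(x, ...) {
  cat(sprintf(
    "<vffr_result> vFFR %.4f (Pd %.1f / Pa %.1f mmHg) at Q %.2f mL/s [%s%s]\n",
    x$vffr, x$Pd, x$Pa, x$Q, x$method,
    if (!is.na(x$iterations)) sprintf(", %d iterations", x$iterations) else ""))
  invisible(x)
}

#' vFFR profile along the vessel from a paired flow study
#'
#' For each arclength station, the pressure drops of the two paired
#' solutions are characterized with [fit_pressure_flow()] and the vFFR at
#' that station computed in closed form, giving a pullback-style vFFR
#' profile. At the inlet the drop is zero and vFFR is 1 by construction;
#' the profile is non-increasing distally up to solver noise.
#'
#' @param solution_pair List of two `flow_solution`s on the same mesh,
#'   differing only in inlet flow.
#' @param Pa Proximal pressure (mmHg).
#' @param R_mv Microvascular resistance (mmHg per mL/s).
#' @param measurement_arclength Optional arclength (mm) at which to report
#'   the headline vFFR; defaults to the last station.
#' @return A `vffr_profile` with the per-station data.frame `profile`
#'   (`arclength`, `f`, `s`, `vffr`) and `vffr` at the measurement point.
#' @export
vffr_profile <- function(solution_pair, Pa = 100, R_mv = 25,
                         measurement_arclength = NULL) {
  stopifnot(length(solution_pair) == 2L)
  s1 <- solution_pair[[1L]]
  s2 <- solution_pair[[2L]]
  if (s1$n_cells != s2$n_cells ||
      nrow(s1$section_pressure) != nrow(s2$section_pressure) ||
      max(abs(s1$section_pressure$arclength -
              s2$section_pressure$arclength)) > 1e-9)
    .stopf("vffr_profile: the two solutions do not share a mesh")
  if (s1$inlet_flow == s2$inlet_flow)
    .stopf("vffr_profile: the two solutions must differ in inlet flow")
  st <- s1$section_pressure$arclength
  dp1 <- (s1$section_pressure$pressure[1] - s1$section_pressure$pressure) /
    PA_PER_MMHG
  dp2 <- (s2$section_pressure$pressure[1] - s2$section_pressure$pressure) /
    PA_PER_MMHG
  q1 <- s1$inlet_flow; q2 <- s2$inlet_flow
  n <- length(st)
  f <- numeric(n); s <- numeric(n); v <- numeric(n)
  for (k in seq_len(n)) {
    if (k == 1L) { f[k] <- 0; s[k] <- 0; v[k] <- 1; next }
    cv <- fit_pressure_flow(q1, dp1[k], q2, dp2[k],
                            measurement_arclength = st[k])
    f[k] <- cv$f; s[k] <- cv$s
    v[k] <- compute_vffr_closed_form(cv, Pa, R_mv)$vffr
  }
  prof <- data.frame(arclength = st, f = f, s = s, vffr = v)
  meas <- measurement_arclength %||% st[n]
  meas <- min(max(meas, st[1]), st[n])
  vffr_at <- approx(st, v, xout = meas)$y
  structure(list(profile = prof, vffr = vffr_at,
                 measurement_arclength = meas, Pa = Pa, R_mv = R_mv,
                 q_points = c(q1, q2)),
            class = "vffr_profile")
}

#' @export
print.vffr_profile <- function(x, ...) {
  cat(sprintf(
    "<vffr_profile> %d stations, vFFR %.4f at %.1f mm (Pa %.0f mmHg, R_mv %.0f)\n",
    nrow(x$profile), x$vffr, x$measurement_arclength, x$Pa, x$R_mv))
  invisible(x)
}

#' Default distal measurement point for a stenosed vessel
#'
#' The headline vFFR is read 10 mm distal to the lesion end (the
#' configurable stand-in for the clinically chosen measurement position),
#' clamped inside the vessel.
#'
#' @param spec A [stenosis_spec()].
#' @param offset_mm Distance distal to the lesion end (mm).
#' @return Arclength (mm).
#' @export
default_measurement_arclength <- function(spec, offset_mm = 10) {
  min(spec$lesion_center + spec$lesion_length / 2 + offset_mm,
      0.98 * spec$vessel_length)
}

#' Full vFFR pipeline for one vessel at one fidelity
#'
#' Meshes the vessel, runs the paired steady simulations (default 1 and
#' 3 mL/s, plug inlet, zero-pressure outlet), fits the quadratic
#' characteristic at the measurement point and computes vFFR in closed
#' form (cross-checked against the pseudo-transient iteration).
#'
#' @param geometry A `vessel_geometry`.
#' @param fidelity A [fidelity_level()] or integer percent.
#' @param flows The two characterization flows (mL/s).
#' @param fluid,controls Solver configuration.
#' @param Pa,R_mv Coupling parameters (mmHg, mmHg/(mL/s)).
#' @param measurement_arclength Measurement arclength (mm); default 10 mm
#'   distal to the lesion end when the geometry carries its spec.
#' @param n_min,n_max Cell budget when `fidelity` is a percent.
#' @return A `vffr_case` list: `vffr`, `curve`, `profile`, `duration_s`
#'   (sum of the two solver durations), `solutions`.
#' @export
vffr_case <- function(geometry, fidelity, flows = c(1, 3),
                      fluid = fluid_properties(),
                      controls = solver_controls(),
                      Pa = 100, R_mv = 25,
                      measurement_arclength = NULL,
                      n_min = 8000, n_max = 160000) {
  stopifnot(length(flows) == 2L, flows[1] != flows[2])
  mesh <- build_mesh(geometry, fidelity, n_min = n_min, n_max = n_max)
  sols <- lapply(flows, function(q)
    solve_steady(mesh, fluid, boundary_conditions(q), controls))
  if (is.null(measurement_arclength) && !is.null(geometry$spec))
    measurement_arclength <- default_measurement_arclength(geometry$spec)
  prof <- vffr_profile(sols, Pa = Pa, R_mv = R_mv,
                       measurement_arclength = measurement_arclength)
  st <- prof$profile$arclength
  k <- which.min(abs(st - prof$measurement_arclength))
  curve <- fit_pressure_flow(
    flows[1],
    (sols[[1]]$section_pressure$pressure[1] -
       sols[[1]]$section_pressure$pressure[k]) / PA_PER_MMHG,
    flows[2],
    (sols[[2]]$section_pressure$pressure[1] -
       sols[[2]]$section_pressure$pressure[k]) / PA_PER_MMHG,
    measurement_arclength = st[k])
  cf <- compute_vffr_closed_form(curve, Pa, R_mv)
  structure(list(
    vffr = cf$vffr, result = cf, curve = curve, profile = prof,
    duration_s = sum(vapply(sols, `[[`, numeric(1), "duration_s")),
    converged = all(vapply(sols, `[[`, logical(1), "converged")),
    n_cells = mesh$cell_count,
    fidelity_percent = mesh$fidelity$percent,
    solutions = sols
  ), class = "vffr_case")
}

#' @export
print.vffr_case <- function(x, ...) {
  cat(sprintf(
    "<vffr_case> vFFR %.4f at fidelity %s%% (%d cells, %.2f s solve time)\n",
    x$vffr, x$fidelity_percent, x$n_cells, x$duration_s))
  invisible(x)
}
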
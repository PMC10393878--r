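test_that("analytic oracles match hand-evaluated closed forms", {
  # 8 mu L Q / (pi R^4) for R = 1.5 mm, L = 30 mm, mu = 3.5 mPa s, Q = 1 mL/s
  expect_equal(poiseuille_dp(1.5e-3, 30e-3, 3.5e-3, 1e-6), 52.8,
               tolerance = 2e-3)
  expect_equal(poiseuille_dp(1.5e-3, 30e-3, 3.5e-3, 2e-6) /
                 poiseuille_dp(1.5e-3, 30e-3, 3.5e-3, 1e-6), 2)
  expect_equal(poiseuille_dp(3e-3, 30e-3, 3.5e-3, 1e-6) /
                 poiseuille_dp(1.5e-3, 30e-3, 3.5e-3, 1e-6), 1 / 16)

  est0 <- stenosis_dp_estimate(3e-3, 0, fluid_properties(), 1e-6)
  expect_equal(est0$inertial_pa, 0)
  e1 <- stenosis_dp_estimate(3e-3, 60, fluid_properties(), 1e-6)
  e2 <- stenosis_dp_estimate(3e-3, 60, fluid_properties(), 2e-6)
  expect_equal(e2$inertial_pa / e1$inertial_pa, 4)
  expect_equal(e2$viscous_pa / e1$viscous_pa, 2)
})

test_that("steady solve on a cylinder conserves mass and matches Poiseuille", {
  sol <- cyl_solution(0.234)
  expect_true(sol$converged)
  expect_identical(sol$convergence_mode, "steady")
  expect_lt(sol$flux_imbalance_rel, 1e-6)
  expect_gte(nrow(sol$section_pressure), 64)
  expect_equal(sol$mass_flux_in, sol$mass_flux_out,
               tolerance = 1e-6)
  # fully developed axial gradient vs the closed form
  dp <- pressure_drop(sol, 16, 27)
  expect_equal(dp, poiseuille_dp(1.5e-3, 11e-3, 3.5e-3, 0.234e-6),
               tolerance = 0.02)
  # linear Poiseuille gradient: equal-length windows have equal drops
  expect_equal(pressure_drop(sol, 14, 20), pressure_drop(sol, 20, 26),
               tolerance = 0.03)
  expect_equal(pressure_drop(sol, 18, 18), 0)
  expect_error(pressure_drop(sol, -2, 10), "outside")
})

test_that("near-zero inflow yields the rest state", {
  geom <- make_stenosed_vessel(cylinder_spec(), 64, 32)
  mesh <- build_mesh(geom, 50, n_min = 300, n_max = 3000)
  sol <- solve_steady(mesh, fluid_properties(), boundary_conditions(1e-6))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$pressure)), 1e-2)       # Pa
  expect_lt(max(abs(sol$velocity)), 1e-3)       # m/s
})

test_that("viscous-dominated pressure drop scales linearly with viscosity", {
  geom <- make_stenosed_vessel(cylinder_spec(), 64, 32)
  mesh <- build_mesh(geom, 75, n_min = 300, n_max = 3000)
  q <- 0.1  # Re ~ 13: viscous dominated
  d1 <- pressure_drop(solve_steady(mesh, fluid_properties(3.5e-3),
                                   boundary_conditions(q)), 15, 27)
  d2 <- pressure_drop(solve_steady(mesh, fluid_properties(7e-3),
                                   boundary_conditions(q)), 15, 27)
  expect_equal(d2 / d1, 2, tolerance = 0.02)
})

test_that("solver is deterministic", {
  geom <- make_stenosed_vessel(lesion_spec(45), 64, 24)
  mesh <- build_mesh(geom, 25, n_min = 300, n_max = 3000)
  fl <- fluid_properties()
  a <- solve_steady(mesh, fl, boundary_conditions(1))
  b <- solve_steady(mesh, fl, boundary_conditions(1))
  expect_identical(a$pressure, b$pressure)
  expect_identical(a$velocity, b$velocity)
  expect_identical(a$residual_history, b$residual_history)
})

test_that("a lesion window drops more pressure than a healthy window", {
  p <- stenosis_pair(60)
  # lesion spans 10-20 mm; healthy proximal window of the same length
  expect_gt(pressure_drop(p$s1, 10, 20), pressure_drop(p$s1, 0, 10))
  # inertial losses make the characteristic super-linear in flow
  meas <- default_measurement_arclength(p$geom$spec)
  expect_gt(pressure_drop(p$s3, 0, meas) / pressure_drop(p$s1, 0, meas), 3)
  # solver lands within a factor 2 of the empirical stenosis correlation
  est <- stenosis_dp_estimate(3e-3, 60, fluid_properties(), 3e-6)
  ratio <- pressure_drop(p$s3, 0, meas) / est$total_pa
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("grid refinement converges the measured pressure drop", {
  # tested from the budget where the discretization enters its asymptotic
  # range; the very coarsest desk meshes approach the limit
  # non-monotonically (see the methods vignette)
  geom <- make_stenosed_vessel(lesion_spec(40), 64, 32)
  fl <- fluid_properties()
  dp <- vapply(c(10, 25, 50, 75, 100), function(pct) {
    m <- build_mesh(geom, pct, n_min = 500, n_max = 5000)
    pressure_drop(solve_steady(m, fl, boundary_conditions(1)), 0, 28)
  }, numeric(1))
  err <- abs(dp - dp[5])
  expect_true(all(diff(err) <= abs(dp[5]) * 0.01))
  expect_lt(err[4], abs(dp[5]) * 0.05)
})

test_that("a high-Reynolds run records a laminar-cap warning", {
  geom <- make_stenosed_vessel(cylinder_spec(), 48, 24)
  mesh <- build_mesh(geom, 25, n_min = 300, n_max = 3000)
  ctl <- solver_controls(re_laminar_cap = 10)
  sol <- solve_steady(mesh, fluid_properties(), boundary_conditions(0.234),
                      ctl)
  expect_true(any(grepl("laminar cap", sol$warnings)))
  expect_gt(sol$reynolds, 10)
})

test_that("non-convergence raises a structured error with residuals", {
  geom <- make_stenosed_vessel(lesion_spec(60), 64, 24)
  mesh <- build_mesh(geom, 25, n_min = 300, n_max = 3000)
  ctl <- solver_controls(max_outer = 8, tol = 1e-12)
  err <- tryCatch(
    solve_steady(mesh, fluid_properties(), boundary_conditions(3), ctl),
    error = function(e) e)
  expect_s3_class(err, "vffrsim_divergence")
  expect_true(is.matrix(err$residual_history))
})
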
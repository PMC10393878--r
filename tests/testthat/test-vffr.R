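test_that("two-point characterization solves the 2x2 system exactly", {
  cv <- fit_pressure_flow(1, 10, 3, 42)
  expect_identical(c(cv$f, cv$s), c(8, 2))
  # exact interpolation of both input points
  expect_equal(predict_dp(cv, 1), 10, tolerance = 1e-15)
  expect_equal(predict_dp(cv, 3), 42, tolerance = 1e-15)
  # purely linear characteristic
  cv2 <- fit_pressure_flow(1, 7, 3, 21)
  expect_equal(cv2$s, 0)
  expect_equal(cv2$f, 7)
  # zero lesion
  cv3 <- fit_pressure_flow(1, 0, 3, 0)
  expect_identical(c(cv3$f, cv3$s), c(0, 0))
  expect_error(fit_pressure_flow(2, 5, 2, 9), "singular")
  expect_error(fit_pressure_flow(-1, 5, 3, 9), "> 0")
  # random exactness property
  set.seed(42)
  for (i in 1:50) {
    q <- sort(runif(2, 0.2, 5)); dp <- runif(2, 0, 60)
    cv <- fit_pressure_flow(q[1], dp[1], q[2], dp[2])
    expect_equal(predict_dp(cv, q[1]), dp[1], tolerance = 1e-12)
    expect_equal(predict_dp(cv, q[2]), dp[2], tolerance = 1e-12)
  }
})

test_that("closed-form vFFR solves the coupled operating point", {
  # unobstructed vessel
  r0 <- compute_vffr_closed_form(fit_pressure_flow(1, 0, 3, 0), 100, 25)
  expect_equal(r0$vffr, 1)
  expect_equal(r0$Q, 4)
  # huge microvascular resistance: flow-limited regime vanishes
  r1 <- compute_vffr_closed_form(fit_pressure_flow(1, 10, 3, 42), 100, 1e6)
  expect_gt(r1$vffr, 0.999)
  # quadratic root evaluated independently
  q_expected <- (-33 + sqrt(33^2 + 4 * 2 * 100)) / (2 * 2)
  r2 <- compute_vffr_closed_form(fit_pressure_flow(1, 10, 3, 42), 100, 25)
  expect_equal(r2$Q, q_expected, tolerance = 1e-12)
  expect_equal(r2$vffr, 25 * q_expected / 100, tolerance = 1e-12)
  expect_equal(r2$Pd, r2$Pa - predict_dp(r2$curve, r2$Q), tolerance = 1e-9)
  expect_error(compute_vffr_closed_form(r2$curve, -1, 25), "Pa and R_mv")
})

test_that("pseudo-transient iteration reaches the same operating point", {
  cv0 <- fit_pressure_flow(1, 0, 3, 0)
  r <- compute_vffr_pseudo_transient(cv0, 100, 25, relaxation = 1)
  expect_equal(r$iterations, 1L)
  expect_equal(r$Q, 4)
  cv <- fit_pressure_flow(1, 10, 3, 42)
  rc <- compute_vffr_closed_form(cv, 100, 25)
  r1 <- compute_vffr_pseudo_transient(cv, 100, 25, relaxation = 1)
  r5 <- compute_vffr_pseudo_transient(cv, 100, 25, relaxation = 0.5)
  expect_equal(r1$vffr, rc$vffr, tolerance = 1e-8)
  expect_equal(r5$vffr, rc$vffr, tolerance = 1e-8)
  expect_false(r1$iterations == r5$iterations)
  expect_error(compute_vffr_pseudo_transient(cv, 100, 25, relaxation = 1.5),
               "relaxation")
})

test_that("methods agree and vFFR is physical over random parameter draws", {
  set.seed(20230421)
  worst <- 0
  for (i in 1:1000) {
    f <- runif(1, 0, 50); s <- runif(1, 0, 50)
    Pa <- runif(1, 60, 140); R <- runif(1, 5, 100)
    cv <- fit_pressure_flow(1, f + s, 3, 3 * f + 9 * s)
    a <- compute_vffr_closed_form(cv, Pa, R)
    b <- compute_vffr_pseudo_transient(cv, Pa, R)
    worst <- max(worst, abs(a$vffr - b$vffr) / a$vffr)
    expect_gt(a$vffr, 0)
    expect_lte(a$vffr, 1)
  }
  expect_lt(worst, 1e-8)
})

test_that("vFFR responds monotonically to lesion and bed parameters", {
  base <- list(f = 8, s = 2, Pa = 100, R = 25)
  v <- function(f, s, R)
    compute_vffr_closed_form(fit_pressure_flow(1, f + s, 3, 3 * f + 9 * s),
                             base$Pa, R)$vffr
  v0 <- v(8, 2, 25)
  expect_lt(v(12, 2, 25), v0)   # more viscous loss
  expect_lt(v(8, 5, 25), v0)    # more inertial loss
  expect_gt(v(8, 2, 50), v0)    # stiffer distal bed
})

test_that("vffr_profile starts at 1 and rejects mismatched solution pairs", {
  sol <- cyl_solution(0.234)
  expect_error(vffr_profile(list(sol, sol)), "differ in inlet flow")
  pair <- fixture("cyl_pair", {
    geom <- make_stenosed_vessel(cylinder_spec(), 64, 32)
    mesh <- build_mesh(geom, 100, n_min = 300, n_max = 3000)
    fl <- fluid_properties()
    list(s1 = solve_steady(mesh, fl, boundary_conditions(1)),
         s3 = solve_steady(mesh, fl, boundary_conditions(3)))
  })
  prof <- vffr_profile(list(pair$s1, pair$s3))
  expect_equal(prof$profile$vffr[1], 1)
  # uniform cylinder: gentle, smooth, monotone decrease (viscous only)
  expect_true(all(diff(prof$profile$vffr) <= 1e-9))
  expect_gt(prof$vffr, 0.9)
  other <- cyl_solution(0.234, budget = c(300, 3000), pct_fid = 50)
  expect_error(vffr_profile(list(pair$s1, other)), "share a mesh")
})

test_that("solved vFFR decreases with stenosis severity", {
  vv <- vapply(c(40, 60, 80), function(pct) {
    p <- stenosis_pair(pct)
    vffr_profile(list(p$s1, p$s3),
                 measurement_arclength =
                   default_measurement_arclength(p$geom$spec))$vffr
  }, numeric(1))
  expect_true(all(diff(vv) < 0))
})

test_that("vffr profile is monotone outside the pressure-recovery zone", {
  p <- stenosis_pair(60)
  prof <- vffr_profile(list(p$s1, p$s3))$profile
  lesion_start <- 10; lesion_end <- 20  # cosine taper over [10, 20] mm
  prox <- prof$vffr[prof$arclength <= lesion_start]
  expect_true(all(diff(prox) <= 0.005))
  # distal of jet reattachment (a few diameters past the lesion end)
  dist <- prof$vffr[prof$arclength >= lesion_end + 6]
  expect_true(all(diff(dist) <= 0.005))
  # static pressure never recovers above its pre-lesion value
  expect_lt(max(dist), min(prox) + 0.005)
})

test_that("measurement point defaults 10 mm distal to the lesion end", {
  sp <- lesion_spec(60)  # lesion ends at 20 mm
  expect_equal(default_measurement_arclength(sp), 29.4)  # clamped 0.98 L
  sp2 <- stenosis_spec(3, 60, 8, 10, vessel_length = 40)
  expect_equal(default_measurement_arclength(sp2), 24)
})
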
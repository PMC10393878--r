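test_that("stenosis_spec validates its bounds with informative errors", {
  expect_error(stenosis_spec(3, 100, 10, 15, vessel_length = 30),
               "stenosis_pct")
  expect_error(stenosis_spec(3, -1, 10, 15, vessel_length = 30),
               "stenosis_pct")
  expect_error(stenosis_spec(-3, 50, 10, 15, vessel_length = 30),
               "reference_diameter")
  expect_error(stenosis_spec(3, 50, 0, 15, vessel_length = 30),
               "lesion_length")
  expect_error(stenosis_spec(3, 50, 10, 4, vessel_length = 30),
               "does not fit")
  expect_error(stenosis_spec(3, 50, 10, 15, eccentricity = 2,
                             vessel_length = 30), "eccentricity")
  sp <- stenosis_spec(3, 60, 10, 15, vessel_length = 30)
  expect_equal(sp$throat_diameter, 1.2)
})

test_that("zero stenosis gives a uniform cylinder", {
  geom <- make_stenosed_vessel(cylinder_spec(), 48, 32)
  expect_true(is_watertight(geom))
  expect_equal(diff(range(geom$radius_profile)), 0)
  prof <- extract_radius_profile(geom, 40)
  # all stations report the reference radius (small polygon-chord deficit)
  expect_lt(max(abs(prof$radius - 1.5)), 0.01)
  expect_lt(diff(range(prof$radius)), 1e-9)
})

test_that("throat diameter and area follow the percent-stenosis definition", {
  geom <- make_stenosed_vessel(lesion_spec(60), 128, 32)
  expect_equal(min(geom$radius_profile) * 2, 1.2, tolerance = 1e-6)
  k <- which.min(geom$radius_profile)
  expect_equal(geom$arclength[k], 15, tolerance = 30 / 128)
  prof <- extract_radius_profile(geom, 128)
  expect_equal(min(prof$radius), 0.6, tolerance = 0.01)
  # area ratio scales as diameter squared
  a_ref <- pi * 1.5^2
  expect_equal(min(prof$area) / a_ref, 0.16, tolerance = 0.01)
})

test_that("surfaces are closed, outward oriented and arclength is monotone", {
  for (sp in list(lesion_spec(30), lesion_spec(85),
                  stenosis_spec(2.5, 50, 8, 10, eccentricity = 0.5,
                                vessel_length = 25),
                  stenosis_spec(3.5, 40, 12, 20, vessel_length = 35,
                                curvature_radius = 80))) {
    geom <- make_stenosed_vessel(sp, 48, 24)
    expect_true(is_watertight(geom))
    expect_gt(vffrsim:::.surface_volume(geom), 0)
    expect_true(all(diff(geom$arclength) > 0))
    expect_true(all(geom$radius_profile > 0))
  }
  expect_error(make_stenosed_vessel(lesion_spec(50), 8, 32), "axial_samples")
  expect_error(make_stenosed_vessel(lesion_spec(50), 32, 4),
               "circumferential_samples")
})

test_that("radius profile round trip recovers random specs within 2%", {
  set.seed(7011)
  for (i in 1:20) {
    sp <- stenosis_spec(
      reference_diameter = runif(1, 2.5, 4),
      stenosis_pct = runif(1, 30, 90),
      lesion_length = runif(1, 6, 14),
      lesion_center = runif(1, 12, 18),
      vessel_length = 30)
    geom <- make_stenosed_vessel(sp, 128, 32)
    prof <- extract_radius_profile(geom, 96)
    truth <- vffrsim:::.spec_radius(sp, prof$arclength)
    expect_lt(max(abs(prof$radius - truth) / truth), 0.02)
    expect_lt(abs(estimate_stenosis_pct(prof) - sp$stenosis_pct), 2)
  }
})

test_that("profile recovery error shrinks monotonically with refinement", {
  sp <- lesion_spec(60)
  err <- vapply(c(32, 64, 128), function(na) {
    geom <- make_stenosed_vessel(sp, na, max(8, na %/% 2))
    prof <- extract_radius_profile(geom, 96)
    truth <- vffrsim:::.spec_radius(sp, prof$arclength)
    max(abs(prof$radius - truth))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))
})

test_that("eccentric lesions preserve the circular cross-section area", {
  sp0 <- lesion_spec(60)
  sp1 <- stenosis_spec(3, 60, 10, 15, eccentricity = 0.8,
                       vessel_length = 30)
  g0 <- make_stenosed_vessel(sp0, 96, 32)
  g1 <- make_stenosed_vessel(sp1, 96, 32)
  p0 <- extract_radius_profile(g0, 64)
  p1 <- extract_radius_profile(g1, 64)
  expect_equal(p1$area, p0$area, tolerance = 1e-6)
  # but the lumen centre is displaced inside the lesion
  k <- which.min(abs(p1$arclength - 15))
  expect_gt(abs(g1$centerline[which.min(g1$radius_profile), 1]), 0.1)
})
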
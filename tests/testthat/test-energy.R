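test_that("watt-hour arithmetic reproduces the published worked examples", {
  expect_equal(round(energy_wh(50, 607.5), 2), 8.44)
  expect_equal(round(energy_wh(295, 31.7), 2), 2.60)
  expect_equal(round(energy_wh(295, 40.5), 2), 3.32)
  expect_equal(energy_wh(123, 0), 0)
  expect_error(energy_wh(-5, 10), "> 0")
  expect_error(energy_wh(50, -1), ">= 0")
})

test_that("campaign cost converts Wh to kWh before pricing", {
  r <- campaign_cost(8.44, 1000, 0.25)
  expect_equal(r$total_kwh, 8.44)
  expect_equal(r$cost, 2.11)
  expect_equal(campaign_cost(8.44, 0, 0.25)$cost, 0)
  expect_equal(campaign_cost(8.44, 1000, 0.50)$cost, 2 * r$cost)
  expect_error(campaign_cost(-1, 10, 0.2), "non-negative")
})

test_that("energy summary converts per-arm durations with constant power", {
  rec <- data.frame(case_id = "x", method = "reference",
                    fidelity_percent = NA_integer_, duration_s = 3600)
  es <- summarize_energy(rec, list(reference = power_model("cpu", 50)))
  expect_equal(es$by_arm$median_wh, 50)
  expect_error(
    summarize_energy(rec, list(other = 50)), "no power model")
  expect_error(power_model("cpu", -1), "> 0")
})

test_that("medians commute with the fixed-power energy transform", {
  set.seed(3)
  n <- 11
  rec <- rbind(
    data.frame(case_id = sprintf("c%02d", 1:n), method = "reference",
               fidelity_percent = NA_integer_,
               duration_s = runif(n, 400, 900)),
    data.frame(case_id = sprintf("c%02d", 1:n), method = "fidelity_sweep",
               fidelity_percent = 100L, duration_s = runif(n, 20, 50)))
  es <- summarize_energy(rec, c(reference = 50, fidelity_100 = 295))
  ref_d <- rec$duration_s[rec$method == "reference"]
  gpu_d <- rec$duration_s[rec$method != "reference"]
  expect_equal(es$by_arm$median_wh[es$by_arm$arm == "reference"],
               50 * median(ref_d) / 3600)
  expect_equal(es$by_arm$median_wh[es$by_arm$arm == "fidelity_100"],
               295 * median(gpu_d) / 3600)
})

test_that("rank-based comparisons are invariant to the power transform", {
  set.seed(4)
  n <- 12
  dur_a <- runif(n, 400, 900)
  dur_b <- runif(n, 20, 50)
  rec <- rbind(
    data.frame(case_id = sprintf("c%02d", 1:n), method = "reference",
               fidelity_percent = NA_integer_, duration_s = dur_a),
    data.frame(case_id = sprintf("c%02d", 1:n), method = "fidelity_sweep",
               fidelity_percent = 10L, duration_s = dur_b))
  es <- summarize_energy(rec, c(reference = 50, fidelity_10 = 50))
  # same power on both arms: the energy test IS the duration test
  w_dur <- wilcoxon_signed_rank(dur_a - dur_b)
  expect_equal(es$comparisons$p_value, w_dur$p_value, tolerance = 1e-12)
})
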
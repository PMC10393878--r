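test_that("accuracy metric follows the printed formula and is symmetric", {
  expect_equal(accuracy_pct(0.80, 0.80), 100)
  expect_equal(accuracy_pct(0.79, 0.80), 98.75)
  expect_equal(accuracy_pct(0.81, 0.80), 98.75)
  expect_equal(accuracy_pct(c(0.7, 0.9), c(0.8, 0.8)), c(87.5, 87.5))
  expect_error(accuracy_pct(0.8, 0), "> 0")
})

test_that("signed-rank p-values equal the exhaustive enumeration oracle", {
  fixtures <- list(
    c(1.2, 0.8, 2.1, 0.4, 1.7, 0.3, 0.9, 1.1, 0.6, 0.5),  # all positive
    c(-0.3, 0.5, 1.2, -0.8, 0.1, 0.9, -1.5, 0.7),
    c(2, -1, 3, -4, 5, -6, 7, 8, -9, 1.5, 0.2, -0.1),
    c(1, 1, -1, 2, -2, 3, 0.5, -0.5),                      # heavy ties
    c(-0.2, -0.4, -0.6, 0.1, -0.9, -1.3, -0.8)
  )
  for (d in fixtures) {
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, signrank_enum_p(d), tolerance = 1e-12)
  }
  # all-positive n = 10: exact two-sided p = 2 / 2^10
  r <- wilcoxon_signed_rank(fixtures[[1]])
  expect_equal(r$p_value, 2 / 1024)
  expect_true(r$exact)
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(99)
  d <- round(rnorm(15), 3)
  mine <- wilcoxon_signed_rank(d)
  ref <- wilcox.test(d, conf.int = TRUE, exact = TRUE, correct = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$median_difference, unname(ref$estimate),
               tolerance = 1e-10)
  expect_equal(mine$conf_int, unname(as.vector(ref$conf.int)),
               tolerance = 1e-10)
  # the discrete achievable level can only meet or exceed the request
  expect_gte(mine$achieved_level, 0.95)
  # large-sample path against the reference's normal approximation
  set.seed(100)
  d40 <- rnorm(40, 0.2)
  mine40 <- wilcoxon_signed_rank(d40)
  ref40 <- wilcox.test(d40, exact = FALSE, correct = TRUE)
  expect_equal(mine40$p_value, ref40$p.value, tolerance = 1e-10)
  expect_false(mine40$exact)
})

test_that("the n = 40 order-statistic median CI attains the 96.15% level", {
  set.seed(11)
  d <- rnorm(40)
  r <- wilcoxon_signed_rank(d, conf_level = 0.95)
  expect_equal(round(100 * r$sign_ci_level, 2), 96.15)
  # CI built from the 14th / 27th order statistics of the differences
  expect_equal(r$median_sign_ci, sort(d)[c(14, 27)])
  # the Walsh-average CI has its own discrete level near the request
  expect_gte(r$achieved_level, 0.95)
})

test_that("antisymmetric differences give a null median and large p", {
  d <- c(0.4, -0.4, 1.1, -1.1, 2.3, -2.3, 0.7, -0.7)
  r <- wilcoxon_signed_rank(d)
  expect_equal(r$median_difference, 0, tolerance = 1e-12)
  expect_gt(r$p_value, 0.9)
  expect_error(wilcoxon_signed_rank(rep(0, 10)), "degenerate")
})

test_that("Bland-Altman limits equal direct mean/sd recomputation", {
  r <- bland_altman(rep(0.02, 5))
  expect_equal(r$bias, 0.02)
  expect_equal(r$loa_low, r$loa_high)
  r2 <- bland_altman(c(-1, 0, 1))
  expect_equal(r2$bias, 0)
  expect_equal(r2$sd, 1)
  expect_equal(c(r2$loa_low, r2$loa_high), c(-1.96, 1.96))
  set.seed(8)
  d <- rnorm(40, 0.005, 0.01)
  r3 <- bland_altman(d)
  expect_equal(r3$bias, sum(d) / 40)
  expect_equal(r3$sd, sqrt(sum((d - mean(d))^2) / 39))
  expect_equal(r3$loa_high, mean(d) + 1.96 * sd(d))
  expect_true(r3$loa_low <= r3$bias && r3$bias <= r3$loa_high)
  expect_error(bland_altman(c(1, 2)), "at least 3")
})

test_that("per-group regression recovers exact fits and detects slopes", {
  x <- c(1:10, 1:10)
  g <- rep(c("a", "b"), each = 10)
  y <- ifelse(g == "a", 2 * x + 1, 2 * x + 5)
  r <- regression_with_slope_compare(x, y, g)
  expect_equal(r$fits$slope, c(2, 2), tolerance = 1e-12)
  expect_equal(r$fits$intercept, c(1, 5), tolerance = 1e-12)
  expect_equal(r$fits$r_squared, c(1, 1), tolerance = 1e-12)
  expect_error(regression_with_slope_compare(rep(1, 20), y, g),
               "zero x-variance")
  expect_error(regression_with_slope_compare(x, y, rep("a", 20)),
               "at least 2 groups")
})

test_that("treat/defer concordance counts threshold crossings", {
  expect_equal(
    concordance_at_threshold(0.79, 0.81)$percent_concordant, 0)
  expect_equal(
    concordance_at_threshold(rep(0.7, 6), rep(0.7, 6))$percent_concordant,
    100)
  ref <- c(0.79, 0.81, 0.5, 0.6, 0.9, 0.95, 0.75, 0.85, 0.4, 0.7)
  test <- c(0.81, 0.79, 0.52, 0.61, 0.88, 0.94, 0.74, 0.86, 0.41, 0.69)
  r <- concordance_at_threshold(ref, test, case_id = letters[1:10])
  expect_equal(r$percent_concordant, 80)
  expect_setequal(r$discordant, c("a", "b"))
})

test_that("sweep summary keeps accuracy and difference consistent", {
  # synthetic benchmark records: 8 cases, reference + two fidelities
  set.seed(5)
  ids <- sprintf("c%02d", 1:8)
  vref <- runif(8, 0.6, 0.95)
  rec <- rbind(
    data.frame(case_id = ids, method = "reference",
               fidelity_percent = NA_integer_, n_cells = 4000,
               duration_s = runif(8, 8, 12), vffr = vref, converged = TRUE,
               stenosis_pct = NA_real_),
    data.frame(case_id = ids, method = "fidelity_sweep",
               fidelity_percent = 10L, n_cells = 400,
               duration_s = runif(8, 1, 2),
               vffr = vref + rnorm(8, 0, 0.02), converged = TRUE,
               stenosis_pct = NA_real_),
    data.frame(case_id = ids, method = "fidelity_sweep",
               fidelity_percent = 100L, n_cells = 2000,
               duration_s = runif(8, 4, 6), vffr = vref, converged = TRUE,
               stenosis_pct = NA_real_))
  sw <- structure(list(records = rec, excluded = character(0),
                       fidelities = c(10, 100), n_min = 200, n_max = 2000,
                       reference_cells = 4000), class = "fidelity_sweep")
  sm <- sweep_summary(sw)
  expect_true(all((sm$pairs$accuracy_pct == 100) ==
                    (sm$pairs$difference == 0)))
  # identical vffr at 100%: accuracy exactly 100, zero bias
  expect_equal(sm$by_fidelity$accuracy_median[2], 100)
  expect_equal(sm$bland_altman$fidelity_100$bias, 0)
  expect_equal(sm$concordance$fidelity_100$percent_concordant, 100)
  # medians use the type-7 convention
  d10 <- sm$pairs$duration_s[sm$pairs$fidelity_percent == 10]
  expect_equal(sm$by_fidelity$duration_median[1],
               unname(quantile(d10, 0.5, type = 7)))
})

test_that("benchmark CSV round trips through the documented schema", {
  rec <- data.frame(case_id = c("a", "b"), method = "fidelity_sweep",
                    fidelity_percent = c(10L, 100L), n_cells = c(400L, 2000L),
                    duration_s = c(1.5, 6.2), vffr = c(0.8, 0.81),
                    converged = TRUE, stenosis_pct = c(55, 55))
  p <- withr::local_tempfile(fileext = ".csv")
  write_benchmark_csv(rec, p)
  back <- read_benchmark_csv(p)
  expect_equal(back$vffr, rec$vffr)
  writeLines("case_id,method\na,reference", p)
  expect_error(read_benchmark_csv(p), "missing columns")
})

test_that("diagnostic plots render without error", {
  set.seed(12)
  ba <- bland_altman(rnorm(20, 0.005, 0.01), means = runif(20, 0.6, 0.95))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot_bland_altman(ba))
})
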
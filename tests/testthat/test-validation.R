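test_that("device intercomparison correction divides by 1 + deviation", {
  s <- measurement_series("P1", "Tc99m-HDP/MDP", 700, c(30, 90),
                          c(10, 6), "A", 45)
  expect_equal(device_correction(s, 0)$h10_uSv_h, s$h10_uSv_h)
  # a device reading 45% low is divided by 0.55
  c1 <- device_correction(s, -0.45)
  expect_equal(c1$h10_uSv_h, s$h10_uSv_h / 0.55)
  # correcting then un-correcting restores the series
  back <- device_correction(c1, 1 / (1 - 0.45) - 1)
  expect_equal(back$h10_uSv_h, s$h10_uSv_h, tolerance = 1e-12)
  expect_error(device_correction(s, -1), "-1")
})

test_that("voiding categories assign to the nearest regime", {
  expect_identical(categorize_voiding(30), "a")
  expect_identical(categorize_voiding(45), "b")
  expect_identical(categorize_voiding(120), "c")
  expect_identical(categorize_voiding(210), "d")
  expect_identical(categorize_voiding(234), "d")
  expect_identical(categorize_voiding(27), "a")
  # boundary goes to the lower category; stable +/- 1 min off boundaries
  expect_identical(categorize_voiding(82.5), "b")
  expect_identical(categorize_voiding(81.5), "b")
  expect_identical(categorize_voiding(83.5), "c")
  expect_identical(categorize_voiding(37.5), "a")
  expect_identical(categorize_voiding(165), "c")
  expect_error(categorize_voiding(0), "positive")
  # regimes expand to the documented schedules
  expect_equal(void_times(voiding_regime("a"), 200), c(30, 90, 150))
  expect_equal(void_times(voiding_regime("d"), 500), c(210, 420))
})

test_that("band comparison flags points against the 95% interval", {
  tg <- seq(0, 240, by = 10)
  sim <- data.frame(time_min = tg, value = 0.02 * exp(-0.005 * tg))
  sim$ci95_low <- sim$value * (1 - 0.24)
  sim$ci95_high <- sim$value * (1 + 0.24)
  # measurements exactly on the central curve are all inside
  m <- measurement_series("P1", "x", 500, c(15, 125),
                          0.02 * exp(-0.005 * c(15, 125)) * 500)
  expect_equal(compare_within_ci(m, sim)$fraction, 1)
  # points far above the band are all outside
  m10 <- measurement_series("P1", "x", 500, c(15, 125),
                            10 * 0.02 * exp(-0.005 * c(15, 125)) * 500)
  expect_equal(compare_within_ci(m10, sim)$fraction, 0)
  m_out <- measurement_series("P1", "x", 500, 300, 1)
  expect_error(compare_within_ci(m_out, sim), "outside")
})

test_that("12% noisy draws fall inside a 24% band about 95% of the time", {
  tg <- seq(0, 240, by = 5)
  sim <- data.frame(time_min = tg, value = 0.02 * exp(-0.004 * tg))
  sim$ci95_low <- sim$value * (1 - 0.24)
  sim$ci95_high <- sim$value * (1 + 0.24)
  ser <- structure(sim[, c("time_min", "value")],
                   class = c("dose_rate_series", "data.frame"))
  m <- generate_measurements(ser, activity_MBq = 600, noise_sd = 0.12,
                             n_points = 50, seed = 123)
  frac <- compare_within_ci(m, sim)$fraction
  p <- 2 * pnorm(0.24 / 0.12) - 1               # ~0.9545
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 50))
})

test_that("morphology ratios reproduce the published benchmark table", {
  ft <- benchmark_morphology_factors()
  rep <- morphology_stats(ft)
  r <- setNames(rep$ratios$max_min_ratio, rep$ratios$region)
  expect_equal(r[["Urinary bladder content"]], 1.8)
  expect_equal(r[["Remainder"]], 1.1)
  expect_equal(r[["Bone surface"]], 1.4)
  # identical factors give ratio 1 and zero RSD
  same <- data.frame(source_region = "Remainder", a = 2, b = 2, c = 2)
  tg <- c(0, 10)
  ser <- replicate(3, structure(data.frame(time_min = tg, value = c(1, 2)),
                                class = c("dose_rate_series", "data.frame")),
                   simplify = FALSE)
  rep2 <- morphology_stats(same, ser)
  expect_equal(rep2$ratios$max_min_ratio, 1)
  expect_equal(rep2$rsd$rsd, c(0, 0))
  expect_error(morphology_stats(data.frame(source_region = "x", a = 1)),
               "two phantoms")
})

test_that("synthetic measurements are seeded and unbiased when noiseless", {
  tg <- seq(0, 200, by = 5)
  ser <- structure(data.frame(time_min = tg, value = 0.02 * exp(-0.01 * tg)),
                   class = c("dose_rate_series", "data.frame"))
  a <- generate_measurements(ser, 700, n_points = 8, seed = 5)
  b <- generate_measurements(ser, 700, n_points = 8, seed = 5)
  expect_identical(a$h10_uSv_h, b$h10_uSv_h)
  expect_identical(a$time_min, b$time_min)
  # zero bias / zero noise points lie on the true curve
  truth <- approx(tg, ser$value, a$time_min)$y * 700
  expect_equal(a$h10_uSv_h, truth, tolerance = 1e-12)
  # empirical relative SD approaches the configured noise
  big <- generate_measurements(ser, 700, noise_sd = 0.1, n_points = 1e4,
                               seed = 6)
  truth_b <- approx(tg, ser$value, big$time_min)$y * 700
  expect_lt(abs(sd(big$h10_uSv_h / truth_b) / 0.1 - 1), 0.03)
})

test_that("measurement series round-trip through CSV", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(patient_id = "P7", pharmaceutical = "18FDG",
                   activity_MBq = 300, time_min = c(20, 60, 100),
                   h10_uSv_per_h = c(8, 6, 4), device_id = "C",
                   first_void_min = 50)
  write.csv(df, tmp, row.names = FALSE)
  back <- read_measurements_csv(tmp)
  expect_length(back, 1)
  expect_equal(back[["P7"]]$h10_uSv_h, c(8, 6, 4))
  expect_equal(back[["P7"]]$activity_MBq, 300)
  unlink(tmp)
})
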
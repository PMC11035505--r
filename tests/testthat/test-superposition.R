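fake_factors <- function(regions, values) {
  data.frame(source_region = regions, value_uSv_h_MBq = values,
             stringsAsFactors = FALSE)
}

# minimal tac_set with prescribed fractions
fake_tacs <- function(regions, times, A) {
  structure(list(times = times, regions = regions,
                 A = matrix(A, nrow = length(regions),
                            dimnames = list(regions, NULL)),
                 model = list(name = "fake")),
            class = "tac_set")
}

test_that("cumulate is the pointwise region-weighted sum", {
  tg <- c(0, 30, 60)
  # one region with constant unit fraction reproduces the factor
  t1 <- fake_tacs("Remainder", tg, rep(1, 3))
  f1 <- fake_factors("Remainder", 0.015)
  expect_equal(cumulate(f1, t1)$value, rep(0.015, 3))
  # all-zero activities give zero
  t0 <- fake_tacs("Remainder", tg, rep(0, 3))
  expect_equal(cumulate(f1, t0)$value, rep(0, 3))
  # two regions at the published female-phantom factors, equal split
  t2 <- fake_tacs(c("Urinary bladder content", "Remainder"), 0,
                  c(0.5, 0.5))
  f2 <- fake_factors(c("Urinary bladder content", "Remainder"),
                     c(2.06e-2, 1.50e-2))
  expect_equal(cumulate(f2, t2)$value, 1.78e-2)
  # a region without a factor errors instead of being dropped
  expect_error(cumulate(f1, t2), "no dose-rate factor")
})

test_that("cumulate is linear and permutation-invariant", {
  set.seed(11)
  regs <- c("Bone", "Kidneys", "Remainder")
  tg <- seq(0, 100, by = 20)
  A <- matrix(runif(18), 3)
  tt <- fake_tacs(regs, tg, A)
  f <- fake_factors(regs, c(0.01, 0.02, 0.015))
  v <- cumulate(f, tt)$value
  # doubling the factors doubles the series
  f2 <- f; f2$value_uSv_h_MBq <- 2 * f$value_uSv_h_MBq
  expect_equal(cumulate(f2, tt)$value, 2 * v)
  # permuting region order changes nothing
  perm <- c(3, 1, 2)
  tt_p <- fake_tacs(regs[perm], tg, A[perm, ])
  expect_equal(cumulate(f, tt_p)$value, v)
})

test_that("log-normal variability transform matches the printed form", {
  expect_equal(lognormal_sd(1, factor = 1), 0)
  expect_equal(lognormal_sd(0, factor = 2), 0)
  expect_equal(lognormal_sd(1, factor = 2, k = 2),
               sqrt(exp((log(2) / 2)^2) - 1), tolerance = 1e-12)
  expect_equal(round(lognormal_sd(1, 2, 2), 3), 0.357)
  # linear in a, monotone increasing in the factor
  expect_equal(lognormal_sd(0.3, 2), 0.3 * lognormal_sd(1, 2))
  fs <- c(1, 1.5, 2, 3, 5)
  expect_true(all(diff(vapply(fs, function(f) lognormal_sd(1, f),
                              numeric(1))) > 0))
  expect_error(lognormal_sd(1, factor = 0.5), ">= 1")
})

test_that("uncertainty propagation reduces correctly and matches sampling", {
  regs <- c("Bone", "Kidneys", "Remainder")
  tg <- 0
  set.seed(21)
  a <- runif(3, 0.05, 0.4)
  C <- runif(3, 0.005, 0.02)
  tt <- fake_tacs(regs, tg, a)
  f <- fake_factors(regs, C)
  uC <- setNames(C * c(0.06, 0.08, 0.05), regs)
  ser <- propagate(f, tt, uC, lognormal_factor = 2, k = 2)
  ua <- lognormal_sd(a, 2, 2)
  U_hand <- sqrt(sum((a * uC)^2) + sum((C * ua)^2))
  expect_equal(ser$U, U_hand, tolerance = 1e-12)
  expect_equal(ser$ci95_high - ser$value, ser$U)
  # single region reduces to the two-term quadrature
  s1 <- propagate(fake_factors("Bone", C[1]), fake_tacs("Bone", 0, a[1]),
                  setNames(uC[1], "Bone"))
  expect_equal(s1$U, sqrt((a[1] * uC[[1]])^2 + (C[1] * ua[1])^2),
               tolerance = 1e-12)
  # all-zero uncertainties give a zero band
  s0 <- propagate(f, tt, setNames(rep(0, 3), regs), lognormal_factor = 1)
  expect_equal(s0$U, 0)
  # Monte Carlo propagation oracle (independent Gaussian perturbations of
  # every factor and fraction; the second-order cross term is < 0.5% here)
  set.seed(22)
  n <- 1e6
  Cs <- matrix(rnorm(3 * n, rep(C, n), rep(uC, n)), 3)
  as <- matrix(rnorm(3 * n, rep(a, n), rep(ua, n)), 3)
  sim <- colSums(Cs * as)
  expect_lt(abs(sd(sim) / U_hand - 1), 0.01)
})

test_that("propagation is permutation-invariant and dominates each term", {
  regs <- c("Bone", "Kidneys", "Remainder")
  set.seed(23)
  a <- runif(3, 0.05, 0.4); C <- runif(3, 0.005, 0.02)
  uC <- setNames(C * 0.07, regs)
  ser <- propagate(fake_factors(regs, C), fake_tacs(regs, 0, a), uC)
  perm <- c(2, 3, 1)
  ser_p <- propagate(fake_factors(regs[perm], C[perm]),
                     fake_tacs(regs[perm], 0, a[perm]), uC[perm])
  expect_equal(ser_p$U, ser$U, tolerance = 1e-12)
  ua <- lognormal_sd(a, 2, 2)
  expect_true(all(ser$U >= pmax(max(a * uC[regs]), max(C * ua)) - 1e-15))
})

test_that("the measurement budget combines in quadrature to percent", {
  expect_identical(measurement_budget(0, 0, 0), 0)
  expect_equal(measurement_budget(0.13), 13)
  pu <- positioning_uncertainty(0.1, 1.0)
  # the inverse-square +/-10 cm at 1 m rule gives ~20%
  expect_equal(round(pu, 2), 0.20)
  expect_equal(pu, (abs(1 / 0.81 - 1) + abs(1 / 1.21 - 1)) / 2,
               tolerance = 1e-12)
  # device 10%, inverse-square positioning, activity 7.5% -> printed 24%
  expect_identical(measurement_budget(0.10, pu, 0.075), 24)
})

test_that("positioning uncertainty vanishes with delta and with distance", {
  expect_equal(positioning_uncertainty(0, 1), 0)
  rs <- c(0.5, 1, 2, 5, 10, 100)
  us <- vapply(rs, function(r) positioning_uncertainty(0.1, r), numeric(1))
  expect_true(all(diff(us) < 0))
  expect_lt(us[length(us)], 0.005)   # ~2 delta / r in the far limit
  expect_error(positioning_uncertainty(1.2, 1), "delta")
})
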
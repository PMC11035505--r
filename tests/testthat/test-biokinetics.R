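test_that("single compartment solves to the closed-form exponential", {
  m <- one_comp_model(rate_out = 0.02)
  lam <- decay_constant(m$nuclide, "per_min")
  tg <- seq(0, 300, by = 10)
  cur <- solve_compartments(m, tg)$blood
  expect_equal(cur$a, exp(-(0.02 + lam) * tg), tolerance = 1e-12)
  # no biological clearance -> pure physical decay
  m0 <- one_comp_model(rate_out = 0)
  cur0 <- solve_compartments(m0, tg)$blood
  expect_equal(cur0$a, exp(-lam * tg), tolerance = 1e-12)
})

test_that("two-compartment chain matches Bateman and the ODE oracle", {
  skip_if_not_installed("deSolve")
  l1 <- 0.03; l2 <- 0.01
  m <- chain_model(l1, l2)
  lam <- decay_constant(m$nuclide, "per_min")
  tg <- seq(0, 360, by = 5)
  curves <- solve_compartments(m, tg)
  # Bateman closed form for the daughter
  bateman <- l1 / (l2 - l1) * (exp(-(l1 + lam) * tg) - exp(-(l2 + lam) * tg))
  expect_equal(curves$B$a, bateman, tolerance = 1e-10)
  orc <- desolve_oracle(m, tg)
  expect_lt(max(abs(curves$A$a - orc[, "A"])), 1e-6)
  expect_lt(max(abs(curves$B$a - orc[, "B"])), 1e-6)
})

test_that("analytic solver matches the ODE oracle on random models", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  tg <- c(0, 15, 60, 180)
  for (rep in 1:100) {
    m <- random_model(sample(2:4, 1))
    curves <- solve_compartments(m, tg)
    orc <- desolve_oracle(m, tg)
    for (cn in m$compartments)
      expect_lt(max(abs(curves[[cn]]$a - orc[, cn])), 1e-6)
  }
})

test_that("voiding schedules expand as stated regimes", {
  s <- voiding_schedule(first_void = 45, interval = 60)
  expect_equal(void_times(s, 240), c(45, 105, 165, 225))
  s2 <- voiding_schedule(first_void = 120)   # interval regime
  expect_equal(void_times(s2, 400), c(120, 240, 360))
  expect_error(voiding_schedule(void_times = c(30, 30)), "increasing")
  expect_error(voiding_schedule(first_void = -5), "positive")
})

test_that("bladder empties completely and instantaneously at each void", {
  m <- bundled_model("Tc99m_HDP_MDP")
  sch <- voiding_regime("b")                 # 45 min then hourly
  tg <- sort(unique(c(seq(0, 300, by = 1), 45, 105, 165, 225)))
  ts <- solve_tacs(m, sch, tg)
  bl <- ts$A["Urinary bladder content", ]
  expect_equal(bl[tg %in% c(45, 105, 165, 225)], rep(0, 4),
               ignore_attr = TRUE)
  expect_true(all(bl >= 0))
  # just before a void the content is strictly positive
  expect_gt(bl[tg == 44], 0)
  # all other regions are continuous through the void
  rem <- ts$A["Remainder", ]
  expect_lt(abs(rem[tg == 45] - rem[tg == 44]), 0.05)
})

test_that("bladder_tac integrates an external inflow against quadrature", {
  lam <- log(2) / 360
  inflow <- function(t) 0.01 * exp(-0.02 * t)
  sch <- voiding_schedule(void_times = 100)
  tg <- seq(0, 200, by = 20)
  b <- bladder_tac(inflow, sch, lam, tg)
  # closed form between voids: int inflow(s) exp(-lam (t-s)) ds
  closed <- function(t, t0) {
    0.01 / (lam - 0.02) * (exp(-0.02 * t) - exp(-0.02 * t0 - lam * (t - t0)))
  }
  expect_equal(b$a[tg == 60], closed(60, 0), tolerance = 1e-8)
  expect_equal(b$a[tg == 100], 0)
  expect_equal(b$a[tg == 160], closed(160, 100), tolerance = 1e-8)
})

test_that("activity is conserved to 1e-9 including decay and voids", {
  m <- bundled_model("Tc99m_HDP_MDP")
  ts <- solve_tacs(m, voiding_regime("a"), seq(0, 480, by = 7))
  total <- colSums(ts$A) + ts$voided_undecayed * ts$decay
  expect_lt(max(abs(total - ts$decay)), 1e-9)
  # regions never exceed the remaining undecayed activity
  expect_true(all(colSums(ts$A) <= ts$decay + 1e-12))
})

test_that("fractional activities start at the injection compartment", {
  m <- bundled_model("F18_FDG")
  a0 <- fractional_activities(m, NULL, 0)
  expect_equal(unname(a0["Blood"]), 1)
  expect_equal(sum(a0), 1, tolerance = 1e-12)
  # immediately after a complete void the sum drops by the bladder content
  sch <- voiding_schedule(void_times = 60)
  pre <- solve_tacs(m, NULL, c(0, 60))          # no voiding
  post <- solve_tacs(m, sch, c(0, 60))          # voided at 60
  drop <- sum(pre$A[, 2]) - sum(post$A[, 2])
  expect_equal(drop, unname(pre$A["Urinary bladder content", 2]),
               tolerance = 1e-12)
})

test_that("time-integrated activity is exact for exponentials and bladders", {
  m <- one_comp_model(rate_out = 0.02)
  lam <- decay_constant(m$nuclide, "per_min")
  ts <- solve_tacs(m, NULL, c(0, 60))
  cur <- region_tac(ts, "Remainder")
  expect_equal(time_integrated_activity(cur, Inf),
               1 / (0.02 + lam) / 60, tolerance = 1e-10)
  # zero curve integrates to zero (bladder never fed before excretion)
  zero <- nmdoserate:::.tac("Kidneys", c(0, 10, 20), c(0, 0, 0))
  expect_equal(time_integrated_activity(zero, 100), 0)
  # bladder with one void: exact piecewise integral vs dense trapezoid
  sch <- voiding_schedule(void_times = 90)
  tsb <- solve_tacs(m, sch, c(0, 240))
  bl <- region_tac(tsb, "Urinary bladder content")
  exact <- time_integrated_activity(bl, 240)
  dense <- seq(0, 240, length.out = 1e5)
  blg <- solve_tacs(m, sch, dense)
  trap <- sum(diff(dense) *
                (head(blg$A["Urinary bladder content", ], -1) +
                   tail(blg$A["Urinary bladder content", ], -1)) / 2) / 60
  expect_lt(abs(exact - trap) / exact, 1e-4)
})

test_that("model validation rejects bad input", {
  expect_error(compartment_model(c(x = "Nowhere"),
                                 data.frame(from = "x", to = "bladder",
                                            rate_per_min = 0.1),
                                 "x", "Tc99m"), "unknown source-region")
  expect_error(compartment_model(c(x = "Blood"),
                                 data.frame(from = "x", to = "bladder",
                                            rate_per_min = -0.1),
                                 "x", "Tc99m"), "negative")
  m <- one_comp_model()
  expect_error(solve_compartments(m, c(0, 10, 5)), "increasing")
})

test_that("bundled models load, round-trip through JSON, and drop at 210", {
  for (nm in c("Tc99m_HDP_MDP", "F18_FDG", "I131_NaI"))
    expect_s3_class(bundled_model(nm), "compartment_model")
  # reference voiding assumption produces the characteristic fast drop of
  # the cumulated bladder content at 210 min post administration
  m <- bundled_model("Tc99m_HDP_MDP")
  ts <- solve_tacs(m, voiding_regime("d"), c(0, 209, 210))
  expect_gt(ts$A["Urinary bladder content", 2], 0.1)
  expect_equal(unname(ts$A["Urinary bladder content", 3]), 0)
})
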
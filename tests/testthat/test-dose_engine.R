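test_that("fluence-to-dose conversion is node-exact and bounded", {
  tab <- nmdoserate:::.h10_table()
  expect_equal(h10_per_fluence(tab$energy_keV), tab$h10, tolerance = 1e-12)
  # between nodes the value lies between the node values
  expect_true(h10_per_fluence(120) > 0.61 && h10_per_fluence(120) < 0.89)
  # hand log-log interpolation between the 100 and 150 keV nodes
  f <- log(140.511 / 100) / log(150 / 100)
  hand <- exp(log(0.61) + f * (log(0.89) - log(0.61)))
  expect_equal(h10_per_fluence(140.511), hand, tolerance = 1e-12)
  expect_error(h10_per_fluence(5), "outside")
})

test_that("unit conversion follows the definition arithmetic", {
  expect_identical(convert_units(0), 0)
  expect_equal(convert_units(1e-15), 3.6)
  x <- c(1e-18, 5e-16)
  expect_equal(convert_units(x) / 3.6e15, x, tolerance = 1e-12)
  expect_error(convert_units(-1))
})

test_that("effective dose applies the tissue weights and remainder rule", {
  w <- tissue_weights()
  expect_equal(sum(w$w_T), 1, tolerance = 1e-12)
  # uniform dose to every tissue gives E = d for any d
  d <- 0.37
  m <- setNames(rep(d, nrow(w)), w$tissue)
  expect_equal(effective_dose(m, m), d, tolerance = 1e-12)
  # male = female reduces to the single-sex weighted sum
  set.seed(1)
  m2 <- setNames(runif(nrow(w)), w$tissue)
  expect_equal(effective_dose(m2, m2), sum(w$w_T * m2), tolerance = 1e-12)
  # two-tissue toy with remainder rule backing the missing tissues
  w2 <- data.frame(tissue = c("lung", "remainder"), w_T = c(0.12, 0.88))
  doses <- c(lung = 1, remainder = 2)
  expect_equal(effective_dose(doses, doses, weights = w2), 1.88)
  expect_error(effective_dose(c(lung = 1), c(lung = 1), weights = w2),
               "missing")
})

test_that("forced-detection tally reproduces the vacuum point source", {
  nuc <- mono_nuclide()
  for (r in c(30, 50, 100, 150, 200)) {
    sc <- vacuum_scene(r)
    tr <- mc_transport(sc, nuc, "src", 200, seed = 1, response = "fluence")
    # in vacuum the estimator is deterministic up to the source-voxel
    # extent: fluence = 1/(4 pi r^2) per emitted particle
    expect_equal(tr$tally_per_particle, 1 / (4 * pi * r^2),
                 tolerance = 2e-3)
  }
})

test_that("uncollided fraction through a slab follows exp(-mu x)", {
  # monoenergetic pencil beam through 5 cm of water
  n <- 11L
  lab <- array(1L, c(n, n, n))          # 5 cm cube at 5 mm voxels? no: 1cm
  lm <- data.frame(label = 1L, region = "slab", material = "water",
                   density = 1, stringsAsFactors = FALSE)
  sc <- toy_scene(lab[1:5, , ], lm, 10, detector_cm = c(0, 0, 0))
  arr <- nmdoserate:::.scene_arrays(sc)
  x <- 5                                 # slab thickness along x (cm)
  mu <- mu_linear(load_material("water"), 140.511)
  set.seed(4)
  res <- nmdoserate:::cpp_mc_transport(
    arr$lab, arr$dims, arr$vox, arr$origin, arr$lab2mat, arr$air_mat,
    arr$e_keV, arr$mu_tot, arr$mu_com,
    nmdoserate:::.h10_table()$energy_keV, nmdoserate:::.h10_table()$h10,
    140.511, 1.0, 0L, numeric(0), integer(0), 0L,
    20000L, 15, TRUE, arr$origin + 1e-6, c(1, 0, 0))
  p_unc <- res$n_uncollided / res$n_histories
  expected <- exp(-mu * x)
  se <- sqrt(expected * (1 - expected) / res$n_histories)
  expect_lt(abs(p_unc - expected), 3 * se + 1e-4)
})

test_that("transport conserves energy and is seed-reproducible", {
  tr1 <- mc_transport(vial_scene(), "Tc99m", "solution", 5000, seed = 9)
  tr2 <- mc_transport(vial_scene(), "Tc99m", "solution", 5000, seed = 9)
  expect_identical(tr1$tally_per_particle, tr2$tally_per_particle)
  expect_identical(tr1$e_deposited_keV, tr2$e_deposited_keV)
  tr3 <- mc_transport(vial_scene(), "Tc99m", "solution", 5000, seed = 10)
  expect_false(identical(tr1$tally_per_particle, tr3$tally_per_particle))
  # emitted = deposited + escaped to float tolerance
  expect_equal(tr1$e_emitted_keV,
               tr1$e_deposited_keV + tr1$e_escaped_keV,
               tolerance = 1e-9)
})

test_that("point kernel reduces to the analytic point source in vacuum", {
  nuc <- mono_nuclide()
  for (r in c(50, 100)) {
    sc <- vacuum_scene(r)
    pk <- point_kernel(sc, nuc, "src", buildup = FALSE)
    expected <- convert_units(h10_per_fluence(140.511) * 1e-12 /
                                (4 * pi * r^2))
    expect_equal(pk$value_uSv_h_MBq, expected, tolerance = 2e-4)
  }
  # doubling the distance quarters the factor
  v1 <- point_kernel(vacuum_scene(50), nuc, "src")$value_uSv_h_MBq
  v2 <- point_kernel(vacuum_scene(100), nuc, "src")$value_uSv_h_MBq
  expect_equal(v1 / v2, 4, tolerance = 1e-3)
})

test_that("point kernel and Monte Carlo agree on benchmark scenes", {
  # vial geometry
  pk <- vial_reference("Tc99m", backend = "point_kernel")
  mc <- vial_reference("Tc99m", n_histories = 5e4, seed = 5)
  expect_lt(abs(pk$value_uSv_h_MBq / mc$value_uSv_h_MBq - 1), 0.15)
  # patient scene at >= 50 cm: the additive region-summed H*(10)
  regs <- c("Urinary bladder content", "Kidneys", "Bone", "Remainder")
  ph <- generate_phantom(164, 60.2, regs, seed = 1, voxel_mm = 10)
  for (gap in c(50, 100)) {
    sc <- build_scene(ph, "point", gap = gap)
    pks <- sum(dose_rate_factors(sc, "Tc99m", regs,
                                 backend = "point_kernel")$value_uSv_h_MBq)
    mcs <- sum(dose_rate_factors(sc, "Tc99m", regs, backend = "mc",
                                 n_histories = 2e4, seed = 3)$value_uSv_h_MBq)
    expect_lt(abs(pks / mcs - 1), 0.15)
  }
})

test_that("H*(10) factors are additive over source regions", {
  # a uniform whole-body source equals the voxel-weighted mean of the
  # per-region factors (deterministic backend)
  regs <- c("Urinary bladder content", "Kidneys", "Bone", "Remainder")
  ph <- generate_phantom(164, 60.2, regs, seed = 1, voxel_mm = 10)
  sc <- build_scene(ph, "point", gap = 100)
  per <- vapply(regs, function(rg)
    point_kernel(sc, "Tc99m", rg)$value_uSv_h_MBq, numeric(1))
  nv <- vapply(regs, function(rg) length(source_voxels(ph, rg)), numeric(1))
  whole <- point_kernel(sc, "Tc99m", "Blood")$value_uSv_h_MBq
  expect_equal(whole, sum(per * nv) / sum(nv), tolerance = 1e-10)
})

test_that("vial reference scales with inverse square at distance", {
  v1 <- vial_reference("Tc99m", distance_cm = 100,
                       backend = "point_kernel")$value_uSv_h_MBq
  v2 <- vial_reference("Tc99m", distance_cm = 200,
                       backend = "point_kernel")$value_uSv_h_MBq
  expect_lt(abs(v1 / v2 / 4 - 1), 0.03)   # air attenuation << geometry
})

test_that("organ doses in a face-to-face scene feed the effective dose", {
  regs <- c("Urinary bladder content", "Kidneys", "Bone", "Remainder")
  ph <- generate_phantom(164, 60.2, regs, seed = 1, voxel_mm = 10)
  cp <- generate_phantom(162.7, 50.8, c("Lungs", "Liver", "Stomach wall",
                                        "Thyroid", "Brain", "Remainder"),
                         seed = 2, voxel_mm = 10)
  sc <- build_scene(ph, "face_to_face", gap = 50, counterpart = cp)
  od <- organ_dose_rates(sc, "Tc99m", "Remainder", 2e4, seed = 6)
  expect_true(all(od >= 0))
  expect_gt(od[["Remainder"]], 0)
  # map counterpart regions onto weighted tissues; remainder backs the rest
  tmap <- c("Lungs" = "lung", "Liver" = "liver", "Stomach wall" = "stomach",
            "Thyroid" = "thyroid", "Brain" = "brain",
            "Remainder" = "remainder", "Bone" = "remainder")
  doses <- tapply(od, tmap[names(od)], mean)
  E <- effective_dose(doses, doses)
  expect_gt(E, 0)
  expect_lt(E, 10 * od[["Remainder"]])
})
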
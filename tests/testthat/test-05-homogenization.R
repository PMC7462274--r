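# periodic voxel homogenization against analytic oracles

test_that("a homogeneous solid returns the base material exactly", {
  mat <- phase_materials()
  fx <- make_fixture("full_solid", resolution = 16)
  ct <- homogenize(fx$grid, mat, loads = c("xx", "xy"))
  m <- effective_moduli(ct)
  expect_equal(m$E_c, 1, tolerance = 1e-6)
  expect_equal(m$G_s, 1, tolerance = 1e-6)
  # shear load case reproduces G = E / (2 (1 + nu)) for an isotropic medium
  expect_equal(ct$C44, 110 / (2 * 1.34), tolerance = 1e-9)
})

test_that("a 50/50 laminate with zero-Poisson phases hits the series bound", {
  mat0 <- phase_materials(110, 0, 1e-3, 0)
  fx <- make_fixture("laminate", resolution = 16, volume_fraction = 0.5)
  ct <- homogenize(fx$grid, mat0, loads = "zz")
  series <- fx$analytic$E_series(110, 1e-3)
  expect_equal(ct$stiffness[3, 3], series, tolerance = 0.01)
  # loading in the plane of the layers reaches the parallel (Voigt) bound
  ct2 <- homogenize(fx$grid, mat0, loads = "xx")
  expect_equal(ct2$stiffness[1, 1], fx$analytic$E_parallel(110, 1e-3),
               tolerance = 0.01)
})

test_that("effective axial modulus respects the Voigt and Reuss bounds", {
  mat <- phase_materials()
  spec <- unit_cell("Gyroid", porosity = 0.5, resolution = 24)
  g <- voxelize(spec, fill = TRUE)
  m <- effective_moduli(homogenize(g, mat, loads = "xx"))
  vf <- mean(g$fill)
  voigt <- vf * mat$E_solid + (1 - vf) * mat$E_void
  reuss <- 1 / (vf / mat$E_solid + (1 - vf) / mat$E_void)
  expect_gt(m$E_e, reuss)
  expect_lt(m$E_e, voigt)
})

test_that("TPMS cells exhibit cubic symmetry under the full load set", {
  mat <- phase_materials()
  spec <- unit_cell("Gyroid", porosity = 0.5, resolution = 24)
  g <- voxelize(spec, fill = TRUE)
  ct <- homogenize(g, mat, loads = c("xx", "yy", "zz", "yz", "xz", "xy"))
  expect_lt(ct$cubic_residual, 0.02)
})

test_that("engineering-modulus extraction follows the cubic closed form", {
  m <- effective_moduli(list(C11 = 2, C12 = 1, C44 = 1),
                        phase_materials(E_solid = 2, nu_solid = 1 / 3))
  expect_equal(m$E_e, 4 / 3)
  expect_equal(m$G_e, 1)
  # degenerate limit C11 = C12 gives a vanishing Young's modulus
  m0 <- effective_moduli(list(C11 = 1, C12 = 1, C44 = 0.5))
  expect_equal(m0$E_e, 0)
  expect_error(effective_moduli(list(C11 = -1, C12 = -2, C44 = 1)),
               "positive")
})

test_that("moduli decrease monotonically with porosity", {
  mat <- phase_materials()
  Ec <- Gs <- numeric(0)
  for (phi in c(0.35, 0.5, 0.65)) {
    spec <- unit_cell("SchwarzP", porosity = phi, resolution = 24)
    m <- effective_moduli(homogenize(voxelize(spec, fill = TRUE), mat,
                                     loads = c("xx", "xy")))
    Ec <- c(Ec, m$E_c); Gs <- c(Gs, m$G_s)
  }
  expect_true(all(diff(Ec) < 0))
  expect_true(all(diff(Gs) < 0))
})

test_that("convergence study flags a resolution-independent geometry at once", {
  spec <- unit_cell("SchwarzP", C = 0, resolution = 16)
  fx <- make_fixture("full_solid", resolution = 16)
  # full solid: identical moduli at any resolution
  mat <- phase_materials()
  cs <- convergence_study(unit_cell("SchwarzP", C = 0, resolution = 16),
                          c(16, 24))
  expect_s3_class(cs, "convergence_study")
  expect_true(all(c("E_c", "G_s", "change_E_c") %in% names(cs)))
  expect_error(convergence_study(spec, 32), "resolutions")
  expect_error(convergence_study(spec, c(32, 16)), "increasing")
})

test_that("homogenize validates its inputs", {
  fe <- make_fixture("empty", resolution = 16)
  expect_error(homogenize(fe$grid), "solid phase is empty")
})
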
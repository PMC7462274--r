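# analytic fixtures: every voxel geometry must reproduce its closed forms

test_that("fixture porosities match their closed forms within 1/resolution", {
  n <- 64
  specs <- list(
    make_fixture("sphere", resolution = n, radius = 0.5),
    make_fixture("laminate", resolution = n, volume_fraction = 0.5),
    make_fixture("square_channel", resolution = n, side = 1.0),
    make_fixture("circular_channel", resolution = n, radius = 0.5))
  for (fx in specs)
    expect_lt(abs(porosity(fx$grid) - fx$analytic$porosity), 1 / n)
  # full solid and empty are exact
  expect_identical(porosity(make_fixture("full_solid", resolution = 16)$grid), 0)
  expect_identical(porosity(make_fixture("empty", resolution = 16)$grid), 1)
})

test_that("sphere surface area matches 4 pi r^2 within 2% at high resolution", {
  fx <- make_fixture("sphere", resolution = 128, radius = 0.5)
  m <- measure_morphology(fx)
  expect_equal(m$surface_area, 4 * pi * 0.5^2, tolerance = 0.02)
  expect_equal(m$porosity, fx$analytic$porosity, tolerance = 1 / 128)
})

test_that("laminate series modulus equals an independent spring-chain oracle", {
  fx <- make_fixture("laminate", resolution = 16, volume_fraction = 0.5)
  # independent 1D oracle: two springs in series, unit areas
  spring_series <- function(E1, E2, f) {
    compliance <- f / E1 + (1 - f) / E2
    1 / compliance
  }
  expect_equal(fx$analytic$E_series(110000, 1), spring_series(110000, 1, 0.5))
  expect_equal(fx$analytic$E_series(110000, 1), 1.99996, tolerance = 1e-4)
  expect_equal(fx$analytic$E_parallel(110000, 1), 55000.5)
})

test_that("channel permeability oracles use the superficial-velocity convention", {
  fc <- make_fixture("circular_channel", edge_length = 2.5, radius = 0.5)
  phi <- pi * 0.5^2 / 2.5^2
  expect_equal(fc$analytic$k, phi * (0.5e-3)^2 / 8)
  fs <- make_fixture("square_channel", edge_length = 2.5, side = 1.0)
  # series coefficient for a square duct: u_mean = c a^2 G / mu, c ~ 0.035144
  expect_equal(scaffoldlab:::square_duct_coefficient(), 0.0351, tolerance = 2e-3)
  expect_equal(fs$analytic$k, (1 / 6.25) * scaffoldlab:::square_duct_coefficient() * 1e-6)
})

test_that("fixtures reject geometry that exceeds the cell", {
  expect_error(make_fixture("sphere", radius = 2), "radius")
  expect_error(make_fixture("circular_channel", radius = 1.3), "radius")
  expect_error(make_fixture("square_channel", side = 3), "side")
  expect_error(make_fixture("laminate", volume_fraction = 1.2), "volume_fraction")
})
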
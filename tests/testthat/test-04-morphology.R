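# iso-surface morphometry and the S/V-porosity quadratic

test_that("degenerate cells have zero inner surface", {
  m <- measure_morphology(make_fixture("full_solid", resolution = 16))
  expect_identical(m$porosity, 0)
  expect_identical(m$surface_area, 0)
  expect_identical(m$sv_ratio, 0)
  m2 <- measure_morphology(make_fixture("empty", resolution = 16))
  expect_identical(m2$surface_area, 0)
})

test_that("a planar interface at mid-height measures one flat cell face", {
  fx <- make_fixture("laminate", resolution = 32, volume_fraction = 0.5)
  m <- measure_morphology(fx)
  expect_equal(m$surface_area, 2.5^2, tolerance = 1e-12)
  expect_equal(m$sv_ratio, 2.5^2 / 2.5^3, tolerance = 1e-12)
})

test_that("sv_ratio is exactly surface_area over nominal volume", {
  spec <- unit_cell("Gyroid", porosity = 0.5, resolution = 32)
  m <- measure_morphology(spec, resolution = 48)
  expect_identical(m$sv_ratio, m$surface_area / m$nominal_volume)
  expect_equal(m$nominal_volume, 2.5^3)
})

test_that("outer cube faces are excluded from the inner surface", {
  # an inscribed sphere touches all six faces; only the spherical interface
  # is counted, never the bounding faces of the cell
  fx <- make_fixture("sphere", edge_length = 2.5, resolution = 128,
                     radius = 1.25)
  m <- measure_morphology(fx)
  expect_equal(m$surface_area, 4 * pi * 1.25^2, tolerance = 0.02)
})

test_that("the S/V quadratic recovers exact coefficients and degenerate data", {
  phi <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  f <- fit_sv_quadratic(phi, -4 * phi^2 + 4 * phi)
  expect_equal(unname(coef(f)), c(-4, 4, 0), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  fc <- fit_sv_quadratic(phi, rep(1.3, 5))
  expect_equal(unname(coef(fc)), c(0, 0, 1.3), tolerance = 1e-10)
  expect_error(fit_sv_quadratic(phi[1:3], phi[1:3]), "at least 4")
  expect_error(fit_sv_quadratic(c(0.4, 0.42, 0.44, 0.46), rep(1, 4)),
               "span")
})

test_that("TPMS surface-to-volume ratio peaks near porosity one half", {
  for (topo in c("SchwarzP", "Diamond")) {
    phis <- c(0.25, 0.4, 0.5, 0.6, 0.75)
    sv <- vapply(phis, function(p) {
      spec <- unit_cell(topo, porosity = p, resolution = 48)
      measure_morphology(spec, resolution = 64)$sv_ratio
    }, 0)
    expect_equal(phis[which.max(sv)], 0.5, tolerance = 0.1)
  }
})

test_that("marching surface area is stable under resolution refinement", {
  spec <- unit_cell("Gyroid", porosity = 0.5, resolution = 32)
  a64 <- measure_morphology(spec, resolution = 64)$surface_area
  a96 <- measure_morphology(spec, resolution = 96)$surface_area
  expect_equal(a64, a96, tolerance = 0.01)
})
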
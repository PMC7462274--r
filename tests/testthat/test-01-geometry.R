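# TPMS nodal equations and strut-lattice fields

test_that("nodal equations evaluate to their closed-form anchor values", {
  L <- 2.5
  expect_equal(tpms_field("SchwarzP", 0, 0, 0), 3)
  expect_equal(tpms_field("Gyroid", 0, 0, 0), 0)
  # equation coordinates (pi/2, pi/2, pi/2) = physical L/4
  expect_equal(tpms_field("Diamond", L / 4, L / 4, L / 4), 1)
  expect_equal(tpms_field("FRD", 0, 0, 0), 10)
  expect_equal(tpms_field("FischerKochS", 0, 0, 0, C = 0.2), -0.2)
})

test_that("topology names are matched case- and punctuation-insensitively", {
  expect_equal(match_topology("schwarz-p"), "SchwarzP")
  expect_equal(match_topology("Fischer-Koch S"), "FischerKochS")
  expect_equal(match_topology("fd_cube"), "FDCube")
  expect_error(match_topology("octet"), "unknown topology")
})

test_that("all eight fields are periodic with the cell edge", {
  set.seed(7)
  L <- 2.5
  x <- runif(100) * L; y <- runif(100) * L; z <- runif(100) * L
  for (topo in scaffold_topologies()) {
    C <- if (scaffoldlab:::is_tpms(topo)) 0.17 else 0.31
    f0 <- scaffold_field(topo, x, y, z, C, L)
    f1 <- scaffold_field(topo, x + L, y - 2 * L, z + 3 * L, C, L)
    expect_lt(max(abs(f0 - f1)), 1e-9)
  }
})

test_that("strut primitives contain cell edges and exclude the body center", {
  L <- 2.5
  # any positive half-width puts an edge midpoint inside the solid
  expect_gt(strut_field("Cube", L / 2, 0, 0, half_width = 0.05), 0)
  expect_gt(strut_field("Cube", 0, L / 2, L, half_width = 0.05), 0)
  # the body center is void for thin struts
  expect_lt(strut_field("Cube", L / 2, L / 2, L / 2, 0.1 * L), 0)
  expect_error(strut_field("Cube", 0, 0, 0, half_width = 2), "half_width")
  expect_error(strut_field("Gyroid", 0, 0, 0, 0.1), "not a strut lattice")
})

test_that("porosity is monotone in the level-set parameter", {
  # decreasing in strut half-width ...
  por_w <- vapply(seq(0.2, 1.0, by = 0.2), function(w) {
    f <- scaffoldlab:::field_center_array("Cube", w, 2.5, 24)
    mean(f < 0)
  }, 0)
  expect_true(all(diff(por_w) < 0))
  # ... and increasing in C for every TPMS field
  for (topo in c("Diamond", "Gyroid", "SchwarzP", "FischerKochS", "FRD")) {
    por_c <- vapply(seq(-0.6, 0.6, by = 0.3), function(C) {
      f <- scaffoldlab:::field_center_array(topo, C, 2.5, 24)
      mean(f < 0)
    }, 0)
    expect_true(all(diff(por_c) > 0))
  }
})

test_that("phase-swap symmetry: porosities at +C and -C sum to one", {
  for (topo in c("SchwarzP", "Gyroid", "Diamond")) {
    for (C in c(0.25, 0.6)) {
      pp <- mean(scaffoldlab:::field_center_array(topo, C, 2.5, 32) < 0)
      pm <- mean(scaffoldlab:::field_center_array(topo, -C, 2.5, 32) < 0)
      expect_equal(pp + pm, 1, tolerance = 0.01)
    }
  }
})

test_that("level-set calibration hits the target porosity", {
  calP <- calibrate_levelset("SchwarzP", 0.5, resolution = 48)
  expect_lt(abs(calP$C), 0.02) # odd-symmetric field splits at C = 0
  calG <- calibrate_levelset("Gyroid", 0.5, resolution = 48)
  expect_lt(abs(calG$C), 0.02)
  calD <- calibrate_levelset("Diamond", 0.54, resolution = 64)
  expect_gte(calD$porosity, 0.539)
  expect_lte(calD$porosity, 0.541)
  expect_error(calibrate_levelset("Gyroid", 0.99), "target_porosity")
})

test_that("voxelization thresholds the field at zero with solid >= 0", {
  fx <- make_fixture("full_solid", resolution = 16)
  expect_equal(porosity(fx$grid), 0)
  fe <- make_fixture("empty", resolution = 16)
  expect_equal(porosity(fe$grid), 1)
  spec <- unit_cell("SchwarzP", C = 0, resolution = 64)
  expect_equal(porosity(voxelize(spec)), 0.5, tolerance = 0.005)
})

test_that("voxel porosity converges with resolution", {
  spec <- unit_cell("Gyroid", porosity = 0.4, resolution = 64)
  p64 <- porosity(voxelize(spec, resolution = 64))
  p128 <- porosity(voxelize(spec, resolution = 128))
  expect_lt(abs(p64 - p128), 0.005)
})

test_that("tiling preserves porosity and occupancy is seamless", {
  spec <- unit_cell("Gyroid", porosity = 0.5, resolution = 24)
  g <- voxelize(spec)
  expect_identical(tile(g, 1), g)
  g2 <- tile(g, 2)
  expect_identical(porosity(g2), porosity(g))
  expect_identical(dim(g2$occupancy), dim(g$occupancy) * 2L)
  # periodic continuity across the internal seam: the field-based occupancy
  # next to the seam must match the opposite unit-cell boundary layer
  n <- dim(g$occupancy)[1]
  expect_identical(g2$occupancy[n + 1, , ], g2$occupancy[1, , ])
})

test_that("sub-voxel fill fractions are consistent with binary occupancy", {
  spec <- unit_cell("SchwarzP", porosity = 0.5, resolution = 24)
  g <- voxelize(spec, fill = TRUE)
  expect_equal(dim(g$fill), dim(g$occupancy))
  expect_true(all(g$fill >= 0 & g$fill <= 1))
  # fill-based solid fraction agrees with center-sample fraction
  expect_equal(mean(g$fill), mean(g$occupancy), tolerance = 0.01)
  # pure voxels agree exactly with the center sample away from interfaces
  pure_solid <- g$fill == 1
  expect_true(all(g$occupancy[pure_solid]))
})

test_that("unit_cell validates its inputs", {
  expect_error(unit_cell("Gyroid"), "exactly one")
  expect_error(unit_cell("Gyroid", C = 0, porosity = 0.5), "exactly one")
  expect_error(unit_cell("Gyroid", C = 0, resolution = 8), "resolution")
  expect_error(unit_cell("Cube", C = 2), "half-width")
  # C outside the field range empties a phase
  expect_error(unit_cell("SchwarzP", C = 4), "phase empty")
})
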
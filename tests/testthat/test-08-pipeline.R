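# study orchestration, determinism, geometry export

test_that("a single-cell smoke study populates every stage", {
  cfg <- study_config(topologies = "SchwarzP", porosities = 0.5,
                      resolution_morphology = 48, resolution_mechanics = 16,
                      resolution_flow = 16, reps_flow = 1, verbose = FALSE)
  s <- run_study(cfg)
  expect_s3_class(s, "scaffold_study")
  expect_equal(nrow(s$cells), 1)
  expect_true(is.finite(s$cells$sv_ratio))
  expect_true(is.finite(s$cells$E_c))
  expect_true(is.finite(s$cells$k))
  expect_true(is.finite(s$cells$k_star))
  expect_equal(s$cells$porosity, 0.5, tolerance = 0.02)
  expect_length(s$manifest$log, 0)
})

test_that("rerunning an identical configuration is byte-identical", {
  base <- function(dir) study_config(
    topologies = "Cube", porosities = c(0.45, 0.6),
    resolution_morphology = 32, resolution_mechanics = 16,
    resolution_flow = 12, reps_flow = 1, output_dir = dir, verbose = FALSE)
  d1 <- tempfile(); d2 <- tempfile()
  suppressWarnings(run_study(base(d1)))
  suppressWarnings(run_study(base(d2)))
  expect_identical(readLines(file.path(d1, "cells.csv")),
                   readLines(file.path(d2, "cells.csv")))
  expect_identical(readLines(file.path(d1, "fits.json")),
                   readLines(file.path(d2, "fits.json")))
})

test_that("stage failures are isolated and logged, not fatal", {
  # porosity 0.94 leaves the Cube strut lattice unreachable -> calibrate fails
  cfg <- study_config(topologies = "SchwarzP", porosities = c(0.5, 0.95 - 1e-9),
                      resolution_morphology = 32, resolution_mechanics = 16,
                      resolution_flow = 12, reps_flow = 1, verbose = FALSE)
  s <- suppressWarnings(run_study(cfg))
  expect_equal(nrow(s$cells), 2)
  expect_true(is.finite(s$cells$E_c[1]))
})

test_that("STL export is consistent with the measured surface area", {
  spec <- unit_cell("Gyroid", porosity = 0.5, resolution = 32)
  f <- tempfile(fileext = ".stl")
  export_geometry(spec, f, "stl")
  con <- file(f, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect_gt(ntri, 0)
  area <- 0
  for (t in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))
    a <- rec[4:6]; b <- rec[7:9]; cc <- rec[10:12]
    u <- b - a; v <- cc - a
    area <- area + 0.5 * sqrt(sum(c(u[2] * v[3] - u[3] * v[2],
                                    u[3] * v[1] - u[1] * v[3],
                                    u[1] * v[2] - u[2] * v[1])^2))
  }
  m <- measure_morphology(spec, resolution = 32)
  expect_equal(area, m$surface_area, tolerance = 0.01)
})

test_that("degenerate surfaces are refused and VTK dimensions are right", {
  fs <- make_fixture("full_solid", resolution = 16)
  expect_warning(r <- export_geometry(fs$grid, tempfile(), "stl"),
                 "refused")
  expect_false(isTRUE(r))
  spec <- unit_cell("SchwarzP", porosity = 0.5, resolution = 16)
  g <- tile(voxelize(spec), 4)
  f <- tempfile(fileext = ".vtk")
  export_geometry(g, f, "vtk")
  head <- readLines(f, n = 5)
  expect_equal(head[5], "DIMENSIONS 64 64 64")
})

test_that("study_config validates the porosity ladder", {
  expect_error(study_config(porosities = c(0.5, 0.4)), "increasing")
  expect_error(study_config(porosities = c(0.01, 0.5)), "0.05")
})
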
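#' Configuration for a full scaffold characterization study
#'
#' Encodes the study design: a set of topologies crossed with a porosity
#' ladder, per-stage voxel resolutions, the tiling used for the flow domain,
#' and the material/fluid constants.
#'
#' @param topologies character vector of topology names.
#' @param porosities strictly increasing ladder in (0.05, 0.95); default
#'   `{0.3, 0.4, 0.5, 0.6, 0.7}`.
#' @param edge_length unit-cell edge, mm.
#' @param resolution_morphology voxels per edge for morphometry.
#' @param resolution_mechanics voxels per edge for homogenization.
#' @param resolution_flow voxels per edge per cell for the Stokes solve.
#' @param reps_flow tiling repetitions per axis of the flow domain.
#' @param materials a [phase_materials()] object.
#' @param fluid a [fluid_spec()] object.
#' @param output_dir if non-NULL, CSV/JSON reports are written there.
#' @param verbose print progress.
#' @return an object of class `study_config`.
#' @export
study_config <- function(topologies = scaffold_topologies(),
                         porosities = c(0.3, 0.4, 0.5, 0.6, 0.7),
                         edge_length = 2.5,
                         resolution_morphology = 128,
                         resolution_mechanics = 32,
                         resolution_flow = 24,
                         reps_flow = 2,
                         materials = phase_materials(),
                         fluid = fluid_spec(),
                         output_dir = NULL,
                         verbose = TRUE) {
  topologies <- vapply(topologies, match_topology, "")
  if (any(porosities <= 0.05 | porosities >= 0.95))
    stop("porosity ladder values must lie in (0.05, 0.95)", call. = FALSE)
  if (length(porosities) > 1 && any(diff(porosities) <= 0))
    stop("porosity ladder must be strictly increasing", call. = FALSE)
  structure(list(
    topologies = unname(topologies), porosities = porosities,
    edge_length = edge_length,
    resolution_morphology = as.integer(resolution_morphology),
    resolution_mechanics = as.integer(resolution_mechanics),
    resolution_flow = as.integer(resolution_flow),
    reps_flow = as.integer(reps_flow),
    materials = materials, fluid = fluid,
    output_dir = output_dir, verbose = isTRUE(verbose)),
    class = "study_config")
}

#' Run the full characterization sweep
#'
#' For every (topology, porosity) cell: calibrates the level-set constant,
#' measures morphology, homogenizes the elastic response (axial + shear load
#' cases), solves Stokes flow through the tiled void domain and evaluates the
#' Kozeny-Carman estimate. Per topology, the scaling fits are computed from
#' the per-cell results: quadratic S/V(phi), Gibson-Ashby E_c(rho), linear
#' G_s(E_c) and the best permeability-porosity family. Failures are isolated
#' per cell and stage: the affected quantities are `NA` and the error is
#' logged, but the sweep continues. The run is fully deterministic: repeated
#' runs of the same configuration produce identical numeric output.
#'
#' @param config a [study_config()].
#' @return an object of class `scaffold_study`: `$cells` (data frame, one row
#'   per topology x porosity), `$fits` (per-topology fit objects), `$ranks`
#'   (orderings at the ladder point closest to porosity 0.5) and `$manifest`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) if (config$verbose) message(sprintf(...))
  rows <- list()
  timings <- list()

  for (topo in config$topologies) {
    for (phi in config$porosities) {
      tcell <- system.time({
        row <- list(topology = topo, porosity_target = phi,
                    porosity = NA_real_, sv_ratio = NA_real_,
                    surface_area = NA_real_,
                    C = NA_real_, C11 = NA_real_, C12 = NA_real_,
                    C44 = NA_real_, E_e = NA_real_, G_e = NA_real_,
                    E_c = NA_real_, G_s = NA_real_, porosity_mech = NA_real_,
                    k = NA_real_, k_star = NA_real_, dP = NA_real_,
                    Q = NA_real_)
        stage <- function(name, expr) {
          tryCatch(expr, error = function(e) {
            log <<- c(log, sprintf("%s phi=%.2f %s: %s",
                                   topo, phi, name, conditionMessage(e)))
            NULL
          })
        }
        spec <- stage("calibrate", unit_cell(
          topo, porosity = phi, edge_length = config$edge_length,
          resolution = config$resolution_mechanics))
        if (!is.null(spec)) {
          row$C <- spec$C
          mo <- stage("morphology", measure_morphology(
            spec, resolution = config$resolution_morphology))
          if (!is.null(mo)) {
            row$porosity <- mo$porosity
            row$sv_ratio <- mo$sv_ratio
            row$surface_area <- mo$surface_area
          }
          me <- stage("mechanics", {
            g <- voxelize(spec, resolution = config$resolution_mechanics,
                          fill = TRUE)
            ct <- homogenize(g, config$materials, loads = c("xx", "xy"))
            list(ct = ct, m = effective_moduli(ct), phi = porosity(g))
          })
          if (!is.null(me)) {
            row$C11 <- me$ct$C11; row$C12 <- me$ct$C12; row$C44 <- me$ct$C44
            row$E_e <- me$m$E_e; row$G_e <- me$m$G_e
            row$E_c <- me$m$E_c; row$G_s <- me$m$G_s
            row$porosity_mech <- me$phi
          }
          fl <- stage("flow", {
            g <- voxelize(spec, resolution = config$resolution_flow)
            solve_flow(tile(g, config$reps_flow), config$fluid)
          })
          if (!is.null(fl)) {
            row$k <- fl$k; row$dP <- fl$dP; row$Q <- fl$Q
          }
          if (!is.null(mo))
            row$k_star <- kozeny_carman(mo$porosity, mo$sv_ratio)
        }
        rows[[length(rows) + 1]] <- row
      })
      timings[[sprintf("%s_%.2f", topo, phi)]] <- unname(tcell["elapsed"])
      say("%s phi=%.2f done (%.1fs)", topo, phi, tcell["elapsed"])
    }
  }

  cells <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))

  fits <- list()
  for (topo in config$topologies) {
    d <- cells[cells$topology == topo, ]
    f <- list()
    f$sv <- tryCatch(fit_sv_quadratic(d$porosity, d$sv_ratio),
                     error = function(e) NULL)
    f$gibson_ashby <- tryCatch(
      fit_gibson_ashby(1 - d$porosity_mech, d$E_c), error = function(e) NULL)
    f$shear_compression <- tryCatch(
      fit_linear_relation(d$E_c, d$G_s), error = function(e) NULL)
    f$permeability <- tryCatch(
      fit_permeability_model(d$porosity_target, d$k, "auto"),
      error = function(e) NULL)
    fits[[topo]] <- f
  }

  mid <- config$porosities[which.min(abs(config$porosities - 0.5))]
  at_mid <- cells[cells$porosity_target == mid, ]
  rank_by <- function(col, decreasing = TRUE) {
    v <- at_mid[[col]]
    at_mid$topology[order(v, decreasing = decreasing, na.last = TRUE)]
  }
  ranks <- list(porosity = mid,
                sv_ratio = rank_by("sv_ratio"),
                E_c = rank_by("E_c"),
                G_s = rank_by("G_s"),
                k = rank_by("k"))

  manifest <- list(
    package = "scaffoldlab",
    version = as.character(utils::packageVersion("scaffoldlab")),
    r_version = R.version.string,
    config = config_as_list(config),
    config_hash = config_hash(config),
    timings_s = timings,
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    log = log)

  study <- structure(list(cells = cells, fits = fits, ranks = ranks,
                          manifest = manifest, config = config),
                     class = "scaffold_study")
  if (!is.null(config$output_dir)) write_study(study, config$output_dir)
  study
}

config_as_list <- function(config) {
  cl <- unclass(config)
  cl$materials <- unclass(cl$materials)
  cl$fluid <- unclass(cl$fluid)
  cl
}

# deterministic polynomial hash of the serialized configuration
config_hash <- function(config) {
  bytes <- as.integer(serialize(config_as_list(config), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  for (topo in unique(study$cells$topology))
    utils::write.csv(study$cells[study$cells$topology == topo, ],
                     file.path(dir, paste0("cells_", topo, ".csv")),
                     row.names = FALSE)
  fits <- lapply(study$fits, function(f) list(
    sv = if (!is.null(f$sv)) c(as.list(coef(f$sv)),
                               r_squared = f$sv$r_squared),
    gibson_ashby = if (!is.null(f$gibson_ashby))
      c(as.list(coef(f$gibson_ashby)),
        r_squared = f$gibson_ashby$r_squared,
        mode = f$gibson_ashby$mode),
    shear_compression = if (!is.null(f$shear_compression))
      c(as.list(coef(f$shear_compression)),
        r_squared = f$shear_compression$r_squared),
    permeability = if (!is.null(f$permeability)) list(
      family = f$permeability$family,
      coefficients = as.list(f$permeability$coefficients),
      r_squared = f$permeability$r_squared)))
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(study$ranks, file.path(dir, "ranks.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.scaffold_study <- function(x, ...) {
  cat(sprintf("Scaffold study: %d topologies x %d porosities\n",
              length(x$config$topologies), length(x$config$porosities)))
  print(x$cells[, c("topology", "porosity_target", "porosity", "sv_ratio",
                    "E_c", "G_s", "k", "k_star")],
        row.names = FALSE, digits = 4)
  if (length(x$manifest$log))
    cat("stage errors:\n", paste(" -", x$manifest$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Export a scaffold geometry
#'
#' Writes the triangulated iso-surface as a binary little-endian STL file, or
#' the occupancy grid as a legacy ASCII VTK structured-points file. For
#' single-cell TPMS exports the marching-tetrahedra surface is watertight up
#' to the cell boundary. A geometry without any phase interface (full solid or
#' empty) yields no surface: the STL export is then refused with a warning.
#'
#' @param x a [unit_cell()] spec or a `voxel_grid`.
#' @param file output path.
#' @param format `"stl"` or `"vtk"`.
#' @param resolution voxelization resolution when `x` is a spec.
#' @return the file path, invisibly (`FALSE` for a refused empty export).
#' @export
export_geometry <- function(x, file, format = c("stl", "vtk"),
                            resolution = NULL) {
  format <- match.arg(format)
  if (inherits(x, "unit_cell_spec"))
    x <- voxelize(x, resolution = resolution)
  stopifnot(inherits(x, "voxel_grid"))
  if (format == "vtk") return(write_vtk_grid(x, file))
  f <- corner_field(x)
  mc <- .cpp_march_tets(as.numeric(f), as.integer(dim(f)), x$voxel_size, TRUE)
  tri <- mc$triangles
  if (is.null(tri) || ncol(tri) == 0) {
    warning("iso-surface is empty; STL export refused")
    return(invisible(FALSE))
  }
  write_stl_binary(tri, file)
  invisible(file)
}

# tri: 3 x (3*ntri) matrix of vertex coordinates, consecutive triples
write_stl_binary <- function(tri, file) {
  ntri <- ncol(tri) / 3
  con <- file(file, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "scaffoldlab binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  zero16 <- as.raw(c(0, 0))
  for (t in seq_len(ntri)) {
    a <- tri[, 3 * t - 2]; b <- tri[, 3 * t - 1]; cc <- tri[, 3 * t]
    u <- b - a; v <- cc - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, a, b, cc)), con, size = 4, endian = "little")
    writeBin(zero16, con)
  }
  invisible(file)
}

write_vtk_grid <- function(grid, file) {
  d <- dim(grid$occupancy)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "scaffoldlab occupancy grid",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("SPACING %g %g %g", grid$voxel_size, grid$voxel_size,
            grid$voxel_size),
    sprintf("POINT_DATA %d", prod(d)),
    "SCALARS occupancy int 1",
    "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(grid$occupancy), collapse = " "), con)
  invisible(file)
}
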
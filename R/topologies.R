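#' Scaffold topologies
#'
#' Eight periodic scaffold unit-cell topologies are supported: five triply
#' periodic minimal surface (TPMS) families defined by trigonometric nodal
#' equations (Diamond, Gyroid, SchwarzP, FischerKochS, FRD) and three
#' strut-based lattices built from square-section strut primitives (Cube,
#' FDCube, Octa).
#'
#' @return `scaffold_topologies()` returns the canonical topology names.
#' @export
scaffold_topologies <- function() {
  c("Diamond", "Gyroid", "SchwarzP", "FischerKochS", "FRD",
    "Cube", "FDCube", "Octa")
}

tpms_topologies <- function() scaffold_topologies()[1:5]

#' @rdname scaffold_topologies
#' @param topology a topology name (case and punctuation insensitive, e.g.
#'   `"schwarz-p"`, `"fischer-koch-s"`, `"fd-cube"`).
#' @export
match_topology <- function(topology) {
  key <- gsub("[^a-z0-9]", "", tolower(as.character(topology)[1]))
  map <- c(
    diamond = "Diamond", d = "Diamond",
    gyroid = "Gyroid", g = "Gyroid",
    schwarzp = "SchwarzP", schwarz = "SchwarzP", primitive = "SchwarzP",
    p = "SchwarzP",
    fischerkochs = "FischerKochS", fischerkoch = "FischerKochS",
    fks = "FischerKochS",
    frd = "FRD", rd = "FRD",
    cube = "Cube",
    fdcube = "FDCube",
    octa = "Octa", octahedron = "Octa")
  if (!key %in% names(map))
    stop("unknown topology '", topology, "'; valid names: ",
         paste(scaffold_topologies(), collapse = ", "), call. = FALSE)
  unname(map[key])
}

is_tpms <- function(topology) match_topology(topology) %in% tpms_topologies()

#' Evaluate a TPMS nodal equation
#'
#' Evaluates the level-set field U(x,y,z) - C of a TPMS topology at physical
#' coordinates in mm. One unit-cell edge spans one full period of the
#' trigonometric equations (physical coordinate p maps to 2*pi*p/edge_length),
#' so the field is periodic with the cell edge in all three axes. The solid
#' phase is the region where the returned value is >= 0.
#'
#' @param topology one of `"Diamond"`, `"Gyroid"`, `"SchwarzP"`,
#'   `"FischerKochS"`, `"FRD"`.
#' @param x,y,z numeric coordinates in mm (recycled to a common length).
#' @param C level-set constant (dimensionless); larger C shrinks the solid.
#' @param edge_length unit-cell edge length in mm.
#' @return numeric vector of field values.
#' @export
tpms_field <- function(topology, x, y, z, C = 0, edge_length = 2.5) {
  topology <- match_topology(topology)
  if (!topology %in% tpms_topologies())
    stop("'", topology, "' is not a TPMS topology", call. = FALSE)
  s <- 2 * pi / edge_length
  x <- x * s; y <- y * s; z <- z * s
  u <- switch(topology,
    Diamond = sin(x) * sin(y) * sin(z) + sin(x) * cos(y) * cos(z) +
      cos(x) * sin(y) * cos(z) + cos(x) * cos(y) * sin(z),
    Gyroid = cos(x) * sin(y) + cos(y) * sin(z) + cos(z) * sin(x),
    SchwarzP = cos(x) + cos(y) + cos(z),
    FischerKochS = cos(2 * x) * sin(y) * cos(z) + cos(2 * y) * sin(z) * cos(x) +
      cos(2 * z) * sin(x) * cos(y),
    FRD = 8 * cos(x) * cos(y) * cos(z) + cos(2 * x) * cos(2 * y) * cos(2 * z) -
      cos(2 * x) * cos(2 * y) + cos(2 * y) * cos(2 * z) +
      cos(2 * z) * cos(2 * x))
  u - C
}

# wrap to the symmetric interval [-P/2, P/2)
wrap_coord <- function(v, P) v - P * round(v / P)

#' Evaluate a strut-lattice signed field
#'
#' Signed implicit field of the strut-based topologies, positive inside the
#' strut solid. Struts have square cross-sections of half-width `half_width`
#' (mm) and the union of the primitives is taken pointwise, so the field is
#' periodic under cell translations. Conventions: `Cube` is the 12 cell edges
#' (3 axis lines per corner under periodicity); `FDCube` adds the 12 face
#' diagonals; `Octa` is the 12 edges of the octahedron whose vertices are the
#' 6 face centers.
#'
#' @inheritParams tpms_field
#' @param half_width strut half-width in mm, in (0, edge_length/2).
#' @return numeric vector, positive in the solid phase.
#' @export
strut_field <- function(topology, x, y, z, half_width, edge_length = 2.5) {
  topology <- match_topology(topology)
  if (is_tpms(topology))
    stop("'", topology, "' is not a strut lattice", call. = FALSE)
  L <- edge_length
  if (half_width < 0 || half_width >= L / 2)
    stop("half_width must lie in (0, edge_length/2)", call. = FALSE)
  cx <- wrap_coord(x, L); cy <- wrap_coord(y, L); cz <- wrap_coord(z, L)
  d <- strut_distance(topology, cx, cy, cz, L)
  half_width - d
}

# Chebyshev-type distance to the nearest strut axis (centered, wrapped coords)
strut_distance <- function(topology, cx, cy, cz, L) {
  ax <- abs(cx); ay <- abs(cy); az <- abs(cz)
  # cube edges: axis lines through the (wrapped) cell corner
  d_cube <- pmin(pmax(ay, az), pmax(ax, az), pmax(ax, ay))
  if (topology == "Cube") return(d_cube)
  if (topology == "FDCube") {
    s2 <- sqrt(2)
    dg <- function(u, t) pmax(abs(wrap_coord(u, L)) / s2, t)
    d_diag <- pmin(
      dg(cx - cy, az), dg(cx + cy, az),
      dg(cy - cz, ax), dg(cy + cz, ax),
      dg(cz - cx, ay), dg(cz + cx, ay))
    return(pmin(d_cube, d_diag))
  }
  # Octa: 12 segments between face centers (+-L/2 on each axis)
  verts <- rbind(c(L / 2, 0, 0), c(-L / 2, 0, 0),
                 c(0, L / 2, 0), c(0, -L / 2, 0),
                 c(0, 0, L / 2), c(0, 0, -L / 2))
  pairs <- which(upper.tri(matrix(TRUE, 6, 6)), arr.ind = TRUE)
  d <- rep(Inf, length(cx))
  for (r in seq_len(nrow(pairs))) {
    a <- verts[pairs[r, 1], ]; b <- verts[pairs[r, 2], ]
    if (all(a + b == 0)) next # opposite vertices: not an edge
    m <- (a + b) / 2
    tvec <- (b - a); half <- sqrt(sum(tvec^2)) / 2; tvec <- tvec / (2 * half)
    # square section: one transverse axis is the coordinate plane normal
    n2 <- as.numeric(a == 0 & b == 0) # coordinate-plane normal of the edge
    n1 <- c(tvec[2] * n2[3] - tvec[3] * n2[2],
            tvec[3] * n2[1] - tvec[1] * n2[3],
            tvec[1] * n2[2] - tvec[2] * n2[1])
    dx <- wrap_coord(cx - m[1], L)
    dy <- wrap_coord(cy - m[2], L)
    dz <- wrap_coord(cz - m[3], L)
    dt <- abs(dx * tvec[1] + dy * tvec[2] + dz * tvec[3])
    d1 <- abs(dx * n1[1] + dy * n1[2] + dz * n1[3])
    d2 <- abs(dx * n2[1] + dy * n2[2] + dz * n2[3])
    ds <- pmax(d1, d2, pmax(dt - half, 0))
    d <- pmin(d, ds)
  }
  d
}

#' Evaluate the implicit field of any supported topology
#'
#' Dispatches to [tpms_field()] (where `C` is the dimensionless level-set
#' constant) or [strut_field()] (where `C` is the strut half-width in mm).
#' Positive values are solid.
#'
#' @inheritParams tpms_field
#' @export
scaffold_field <- function(topology, x, y, z, C, edge_length = 2.5) {
  topology <- match_topology(topology)
  if (is_tpms(topology)) tpms_field(topology, x, y, z, C, edge_length)
  else strut_field(topology, x, y, z, C, edge_length)
}

#' Unit-cell specification
#'
#' Describes one periodic scaffold microstructure: a topology plus either the
#' level-set constant `C` (TPMS, dimensionless; strut lattices, half-width in
#' mm) or a target porosity to which `C` is calibrated by bisection.
#'
#' @param topology a topology name, see [scaffold_topologies()].
#' @param C level-set constant / strut half-width. Exactly one of `C` and
#'   `porosity` must be given.
#' @param porosity target void volume fraction in (0.05, 0.95).
#' @param edge_length cell edge in mm (default 2.5).
#' @param resolution voxels per cell edge (integer >= 16).
#' @return an object of class `unit_cell_spec`.
#' @examples
#' cell <- unit_cell("Gyroid", porosity = 0.5, resolution = 32)
#' cell$C # ~0 by the phase-swap symmetry of the gyroid equation
#' @export
unit_cell <- function(topology, C = NULL, porosity = NULL, edge_length = 2.5,
                      resolution = 64) {
  topology <- match_topology(topology)
  stopifnot(edge_length > 0)
  resolution <- as.integer(resolution)
  if (resolution < 16) stop("resolution must be >= 16", call. = FALSE)
  if (is.null(C) == is.null(porosity))
    stop("give exactly one of 'C' and 'porosity'", call. = FALSE)
  if (!is.null(porosity)) {
    cal <- calibrate_levelset(topology, porosity, edge_length = edge_length,
                              resolution = resolution)
    C <- cal$C
  }
  if (!is_tpms(topology) && (C <= 0 || C >= edge_length / 2))
    stop("strut half-width must lie in (0, edge_length/2)", call. = FALSE)
  spec <- structure(
    list(topology = topology, C = C, edge_length = edge_length,
         resolution = resolution),
    class = "unit_cell_spec")
  # both phases must be non-empty
  p <- spec_porosity(spec)
  if (p <= 0 || p >= 1)
    stop("level-set constant leaves one phase empty (porosity ", p, ")",
         call. = FALSE)
  spec
}

#' @export
print.unit_cell_spec <- function(x, ...) {
  cat("Scaffold unit cell:", x$topology, "\n")
  cat(sprintf("  C = %.6g, edge = %g mm, resolution = %d^3\n",
              x$C, x$edge_length, x$resolution))
  cat(sprintf("  voxel porosity = %.4f\n", spec_porosity(x)))
  invisible(x)
}

# voxel-center coordinates for a resolution/edge pair
voxel_centers <- function(resolution, edge_length) {
  (seq_len(resolution) - 0.5) * edge_length / resolution
}

# field sampled at voxel centers, as a resolution^3 array
field_center_array <- function(topology, C, edge_length, resolution) {
  xs <- voxel_centers(resolution, edge_length)
  n <- resolution
  g <- array(0, c(n, n, n))
  y <- rep(xs, each = n)
  for (k in seq_len(n)) {
    g[, , k] <- scaffold_field(topology, rep(xs, n), y, rep(xs[k], n * n),
                               C, edge_length)
  }
  g
}

# porosity of a spec measured on its own voxel grid
spec_porosity <- function(spec, resolution = spec$resolution) {
  f <- field_center_array(spec$topology, spec$C, spec$edge_length, resolution)
  mean(f < 0)
}

#' Calibrate the level-set constant to a target porosity
#'
#' Finds by bisection the level-set constant (TPMS) or strut half-width
#' (strut lattices) at which the voxel-measured porosity matches the target.
#' Porosity is monotone in the parameter (increasing in C for TPMS,
#' decreasing in half-width for struts), which the bisection exploits.
#'
#' @inheritParams unit_cell
#' @param target_porosity void fraction in (0.05, 0.95).
#' @param tol porosity tolerance (default 1e-3).
#' @param max_iter bisection iteration cap.
#' @return list with elements `C` (the calibrated parameter) and `porosity`
#'   (the achieved voxel porosity).
#' @export
calibrate_levelset <- function(topology, target_porosity, edge_length = 2.5,
                               resolution = 64, tol = 1e-3, max_iter = 60) {
  topology <- match_topology(topology)
  if (target_porosity <= 0.05 || target_porosity >= 0.95)
    stop("target_porosity must lie in (0.05, 0.95)", call. = FALSE)
  n <- as.integer(resolution)
  if (is_tpms(topology)) {
    # porosity(C) = fraction{U < C}, increasing in C
    u <- field_center_array(topology, 0, edge_length, n)
    por <- function(C) mean(u < C)
    lo <- min(u); hi <- max(u)
    lo_p <- por(lo); hi_p <- por(hi)
    increasing <- TRUE
  } else {
    # porosity(w) = fraction{d > w}, decreasing in half-width w
    h <- edge_length / n
    d <- -field_center_array(topology, 0, edge_length, n)
    por <- function(w) mean(d > w)
    lo <- h / 2; hi <- edge_length / 2 - h / 2
    lo_p <- por(lo); hi_p <- por(hi)
    increasing <- FALSE
  }
  pmin_ <- min(lo_p, hi_p); pmax_ <- max(lo_p, hi_p)
  if (target_porosity < pmin_ - tol || target_porosity > pmax_ + tol)
    stop(sprintf(
      "target porosity %.3f unreachable for %s: achievable range [%.3f, %.3f]",
      target_porosity, topology, pmin_, pmax_), call. = FALSE)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p <- por(mid)
    if (abs(p - target_porosity) <= tol && it > 1) break
    up <- if (increasing) p < target_porosity else p > target_porosity
    if (up) lo <- mid else hi <- mid
  }
  if (abs(p - target_porosity) > tol) {
    # Grid porosity is a step function of the parameter; strut-lattice
    # distance fields share exact values across whole voxel planes, so the
    # steps can exceed tol. Snap to the midpoint of the step whose porosity
    # is closest to the target.
    vals <- sort(if (increasing) as.numeric(u) else as.numeric(d))
    nv <- length(vals)
    idx <- max(1L, min(nv - 1L,
                       round(if (increasing) target_porosity * nv
                             else (1 - target_porosity) * nv)))
    best <- NULL
    for (i in unique(pmax(1L, pmin(nv - 1L, idx + (-1:1))))) {
      cand <- (vals[i] + vals[i + 1]) / 2
      pc <- por(cand)
      if (is.null(best) || abs(pc - target_porosity) < abs(best$p - target_porosity))
        best <- list(C = cand, p = pc)
    }
    mid <- best$C; p <- best$p
    if (abs(p - target_porosity) > tol)
      warning(sprintf(
        "voxel porosity is quantized at this resolution: closest achievable %.4f for target %.4f",
        p, target_porosity))
  }
  list(C = mid, porosity = p)
}

#' Voxelize a unit cell
#'
#' Samples the implicit field at voxel centers and thresholds it at zero
#' (solid = field >= 0). Center sampling makes the voxel phase fraction an
#' unbiased estimator of the true volume fraction. Optionally computes
#' sub-voxel solid fill fractions (by supersampling) and interface normals
#' (from the field gradient), which the homogenization solver uses for
#' composite interface voxels.
#'
#' @param spec a [unit_cell()] specification.
#' @param resolution overrides `spec$resolution`.
#' @param fill if `TRUE`, compute sub-voxel fill fractions and normals.
#' @param supersample sub-samples per voxel edge used for the fill fractions.
#' @return an object of class `voxel_grid` with elements `occupancy`
#'   (logical array), `voxel_size` (mm), `origin` (mm), `field` (field values
#'   at voxel centers), and optionally `fill`.
#' @export
voxelize <- function(spec, resolution = NULL, fill = FALSE, supersample = 4) {
  stopifnot(inherits(spec, "unit_cell_spec"))
  n <- as.integer(if (is.null(resolution)) spec$resolution else resolution)
  if (n < 16) stop("resolution must be >= 16", call. = FALSE)
  f <- field_center_array(spec$topology, spec$C, spec$edge_length, n)
  g <- new_voxel_grid(f >= 0, voxel_size = spec$edge_length / n,
                      origin = c(0, 0, 0), field = f, spec = spec)
  if (fill) {
    ff <- fill_fractions(spec, n, supersample)
    g$fill <- ff$fill
    g$fill_oct <- ff$oct
  }
  g
}

# Sub-voxel solid fill fractions by layer-chunked supersampling. Returns the
# per-voxel fill plus per-octant fills (n x n x n x 8, octant bit order
# x + 2y + 4z), which feed the per-Gauss-point composite material of the
# homogenization solver. `s` must be even.
fill_fractions <- function(spec, n, s = 4) {
  stopifnot(s %% 2 == 0)
  L <- spec$edge_length
  h <- L / n
  half <- s / 2
  sub <- ((seq_len(s)) - 0.5) * h / s
  xs <- as.vector(outer(sub, (seq_len(n) - 1) * h, "+")) # sub index fastest
  oct <- array(0, c(n, n, n, 8))
  nx <- n * s
  xv <- rep(xs, nx)
  yv <- rep(xs, each = nx)
  lo <- seq_len(half); hi <- half + lo
  for (k in seq_len(n)) {
    acc <- array(0, c(n, n, 8))
    for (sz in seq_len(s)) {
      zk <- (k - 1) * h + sub[sz]
      oz <- if (sz <= half) 0L else 4L
      v <- scaffold_field(spec$topology, xv, yv, rep(zk, nx * nx), spec$C, L)
      a <- array(v >= 0, c(s, n, s, n))   # (sub-x, vox-x, sub-y, vox-y)
      for (ox in 0:1) {
        b <- colSums(a[if (ox == 0) lo else hi, , , , drop = FALSE])
        for (oy in 0:1) {
          q <- 1L + ox + 2L * oy + oz
          acc[, , q] <- acc[, , q] +
            colSums(aperm(b[, if (oy == 0) lo else hi, , drop = FALSE],
                          c(2, 1, 3)))
        }
      }
    }
    oct[, , k, ] <- acc / half^3
  }
  list(fill = rowMeans(oct, dims = 3), oct = oct)
}

new_voxel_grid <- function(occupancy, voxel_size, origin = c(0, 0, 0),
                           field = NULL, spec = NULL, fill = NULL) {
  structure(
    list(occupancy = occupancy, voxel_size = voxel_size, origin = origin,
         field = field, spec = spec, fill = fill),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("Voxel grid %d x %d x %d, voxel %.4g mm (box %.4g x %.4g x %.4g mm)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  porosity = %.4f\n", porosity(x)))
  invisible(x)
}

#' Porosity of a voxel grid
#'
#' Void volume fraction: the fraction of voxels not occupied by solid.
#'
#' @param x a `voxel_grid`.
#' @return numeric in [0, 1].
#' @export
porosity <- function(x) {
  stopifnot(inherits(x, "voxel_grid"))
  mean(!x$occupancy)
}

#' Tile a unit cell periodically
#'
#' Repeats the grid `reps` times along each axis. Tiling preserves phase
#' fractions exactly, and for periodic fields the occupancy is continuous
#' across the internal seams.
#'
#' @param grid a `voxel_grid`.
#' @param reps integer >= 1.
#' @return a `voxel_grid` covering a `reps`-cubed assembly.
#' @export
tile <- function(grid, reps) {
  stopifnot(inherits(grid, "voxel_grid"))
  reps <- as.integer(reps)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (reps == 1) return(grid)
  n <- dim(grid$occupancy)
  ix <- rep(seq_len(n[1]), reps)
  iy <- rep(seq_len(n[2]), reps)
  iz <- rep(seq_len(n[3]), reps)
  g <- new_voxel_grid(grid$occupancy[ix, iy, iz], grid$voxel_size, grid$origin,
                      field = if (!is.null(grid$field)) grid$field[ix, iy, iz],
                      spec = grid$spec,
                      fill = if (!is.null(grid$fill)) grid$fill[ix, iy, iz])
  if (!is.null(grid$fill_oct)) g$fill_oct <- grid$fill_oct[ix, iy, iz, ]
  g$reps <- reps
  g
}
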
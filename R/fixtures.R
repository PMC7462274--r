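#' Analytic validation fixtures
#'
#' Generates voxel geometries with closed-form morphological, elastic and flow
#' properties, so that every downstream stage (morphometry, homogenization,
#' Stokes permeability) can be checked against independent analytic values.
#' All fixtures are deterministic.
#'
#' Kinds and their closed forms:
#' \describe{
#'   \item{`full_solid` / `empty`}{porosity exactly 0 / 1, zero inner surface.}
#'   \item{`laminate`}{solid slab of the given volume fraction normal to
#'     `layer_normal`; porosity `1 - volume_fraction`, one planar interface of
#'     area `edge^2`; Voigt (parallel) and Reuss (series) bounds of a
#'     two-phase stack are supplied as closed-form functions of the phase
#'     moduli (exact for zero-Poisson phases).}
#'   \item{`sphere`}{solid sphere of radius `radius` at the cell center;
#'     porosity `1 - (4/3) pi r^3 / L^3`, surface `4 pi r^2`.}
#'   \item{`square_channel` / `circular_channel`}{straight void channel along
#'     z through an otherwise solid cell; Poiseuille permeability in the
#'     superficial-velocity (Darcy) convention, `k = phi r^2 / 8` for the
#'     circular channel and `k = phi c a^2` for the square channel (series
#'     coefficient `c` evaluated from the exact duct solution).}
#' }
#'
#' @param kind fixture kind, see Details.
#' @param edge_length cell edge, mm.
#' @param resolution voxels per edge.
#' @param volume_fraction solid fraction of the laminate slab.
#' @param layer_normal `"x"`, `"y"` or `"z"`.
#' @param radius sphere/channel radius, mm.
#' @param side square-channel side, mm.
#' @return an object of class `scaffold_fixture`: list with the `voxel_grid`
#'   (`$grid`) and the closed-form property record (`$analytic`).
#' @export
make_fixture <- function(kind = c("full_solid", "empty", "laminate", "sphere",
                                  "square_channel", "circular_channel"),
                         edge_length = 2.5, resolution = 64,
                         volume_fraction = 0.5, layer_normal = "z",
                         radius = 0.5, side = 1.0) {
  kind <- match.arg(kind)
  L <- edge_length
  n <- as.integer(resolution)
  stopifnot(L > 0, n >= 16)
  xs <- voxel_centers(n, L)
  cc <- L / 2

  field_fun <- switch(kind,
    full_solid = function(x, y, z) rep(1, length(x)),
    empty = function(x, y, z) rep(-1, length(x)),
    laminate = {
      if (volume_fraction <= 0 || volume_fraction >= 1)
        stop("volume_fraction must lie in (0, 1)", call. = FALSE)
      ax <- match(layer_normal, c("x", "y", "z"))
      if (is.na(ax)) stop("layer_normal must be x, y or z", call. = FALSE)
      cut <- volume_fraction * L
      function(x, y, z) cut - list(x, y, z)[[ax]]
    },
    sphere = {
      if (radius <= 0 || radius > L / 2)
        stop("sphere radius must lie in (0, edge_length/2]", call. = FALSE)
      function(x, y, z)
        radius - sqrt((x - cc)^2 + (y - cc)^2 + (z - cc)^2)
    },
    square_channel = {
      if (side <= 0 || side >= L)
        stop("channel side must lie in (0, edge_length)", call. = FALSE)
      function(x, y, z) pmax(abs(x - cc), abs(y - cc)) - side / 2
    },
    circular_channel = {
      if (radius <= 0 || radius >= L / 2)
        stop("channel radius must lie in (0, edge_length/2)", call. = FALSE)
      function(x, y, z) sqrt((x - cc)^2 + (y - cc)^2) - radius
    })

  f <- array(0, c(n, n, n))
  yv <- rep(xs, each = n)
  for (k in seq_len(n))
    f[, , k] <- field_fun(rep(xs, n), yv, rep(xs[k], n * n))

  analytic <- switch(kind,
    full_solid = list(porosity = 0, surface_area = 0, sv_ratio = 0),
    empty = list(porosity = 1, surface_area = 0, sv_ratio = 0),
    laminate = list(
      porosity = 1 - volume_fraction,
      surface_area = L^2, sv_ratio = L^2 / L^3,
      volume_fraction = volume_fraction,
      layer_normal = layer_normal,
      E_series = function(E1, E2)
        1 / (volume_fraction / E1 + (1 - volume_fraction) / E2),
      E_parallel = function(E1, E2)
        volume_fraction * E1 + (1 - volume_fraction) * E2),
    sphere = list(
      porosity = 1 - (4 / 3) * pi * radius^3 / L^3,
      surface_area = 4 * pi * radius^2,
      sv_ratio = 4 * pi * radius^2 / L^3, radius = radius),
    square_channel = {
      phi <- side^2 / L^2
      list(porosity = phi,
           surface_area = 4 * side * L, sv_ratio = 4 * side / L^2,
           k = phi * square_duct_coefficient() * side^2 * 1e-6, # m^2
           side = side)
    },
    circular_channel = {
      phi <- pi * radius^2 / L^2
      list(porosity = phi,
           surface_area = 2 * pi * radius * L,
           sv_ratio = 2 * pi * radius / L^2,
           k = phi * radius^2 / 8 * 1e-6, # m^2
           radius = radius)
    })

  grid <- new_voxel_grid(f >= 0, voxel_size = L / n, origin = c(0, 0, 0),
                         field = f,
                         spec = structure(list(kind = kind, edge_length = L,
                                               resolution = n,
                                               field_fun = field_fun),
                                          class = "fixture_spec"))
  structure(list(grid = grid, analytic = analytic, kind = kind),
            class = "scaffold_fixture")
}

# mean-velocity coefficient c of a square duct (u_mean = c * a^2 * G / mu),
# from the exact eigenfunction series of Poiseuille flow in a square
square_duct_coefficient <- function(nterms = 200) {
  n <- seq(1, 2 * nterms - 1, by = 2)
  series <- sum(tanh(n * pi / 2) / n^5)
  (1 / 4) * (1 / 3 - (64 / pi^5) * series)
}

#' @export
print.scaffold_fixture <- function(x, ...) {
  cat("Analytic fixture:", x$kind, "\n")
  cat(sprintf("  grid %d^3, analytic porosity %.4f\n",
              dim(x$grid$occupancy)[1], x$analytic$porosity))
  invisible(x)
}
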
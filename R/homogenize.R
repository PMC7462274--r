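#' Effective elasticity tensor by periodic voxel homogenization
#'
#' Solves periodic cell problems on the voxel grid with trilinear hexahedral
#' elements: a macroscopic strain of magnitude `strain` is imposed through the
#' affine/fluctuation split and the volume-averaged stress yields one column
#' of the effective stiffness per load case (the result is independent of the
#' magnitude — linear elasticity). The default load set mirrors the standard
#' three-load protocol for cubic microstructures: two uniaxial strains and one
#' shear. Voxels cut by the phase interface are assigned the exact rank-1
#' laminate (Backus) stiffness at their sub-voxel fill fraction, oriented
#' along the field gradient, when the grid carries fill fractions (see
#' [voxelize()] with `fill = TRUE`); otherwise voxels are binary solid/void.
#'
#' @param grid a `voxel_grid` (a single unit cell).
#' @param materials a [phase_materials()] object.
#' @param loads character vector from `c("xx","yy","zz","yz","xz","xy")`:
#'   macroscopic strain components to impose, one solve each.
#' @param strain macroscopic strain magnitude (engineering), default 0.01.
#' @param tol relative-residual tolerance of the conjugate-gradient solver.
#' @param maxit iteration cap for the solver.
#' @return an object of class `elasticity_tensor`: the measured entries of the
#'   6x6 stiffness (GPa, `NA` where no load case informs them), cubic-symmetry
#'   accessors `C11`, `C12`, `C44`, the cubic-symmetry residual, and solver
#'   diagnostics.
#' @seealso [effective_moduli()], [convergence_study()]
#' @export
homogenize <- function(grid, materials = phase_materials(),
                       loads = c("xx", "yy", "xy"), strain = 0.01,
                       tol = 1e-6, maxit = 10000) {
  stopifnot(inherits(grid, "voxel_grid"))
  all_loads <- c("xx", "yy", "zz", "yz", "xz", "xy")
  loads <- match.arg(loads, all_loads, several.ok = TRUE)
  dims <- dim(grid$occupancy)
  if (!any(grid$occupancy)) stop("solid phase is empty", call. = FALSE)
  h <- grid$voxel_size

  mats <- build_material_map(grid, materials)
  Cs <- iso_stiffness(materials$E_solid, materials$nu_solid)
  Cv <- iso_stiffness(materials$E_void, materials$nu_void)

  Cmat <- matrix(NA_real_, 6, 6)
  iters <- numeric(0); relres <- numeric(0)
  for (ld in loads) {
    e <- numeric(6)
    e[match(ld, all_loads)] <- strain
    sol <- .cpp_homogenize(mats$id, as.integer(dims), h,
                           as.numeric(t(Cs)), as.numeric(t(Cv)),
                           mats$comp, e, tol, as.integer(maxit))
    if (sol$relres > tol && sol$iterations >= maxit)
      stop(sprintf(
        "homogenization solver did not converge for load '%s': relative residual %.3g after %d iterations",
        ld, sol$relres, sol$iterations), call. = FALSE)
    Cmat[, match(ld, all_loads)] <- sol$sigma / strain
    iters <- c(iters, sol$iterations); relres <- c(relres, sol$relres)
  }

  axial <- diag(Cmat)[1:3]
  coup <- c(Cmat[2, 1], Cmat[3, 1], Cmat[1, 2], Cmat[3, 2], Cmat[1, 3],
            Cmat[2, 3])
  shear <- diag(Cmat)[4:6]
  spread <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    (max(v) - min(v)) / abs(mean(v))
  }
  structure(list(
    stiffness = Cmat,
    C11 = mean(axial, na.rm = TRUE),
    C12 = mean(coup, na.rm = TRUE),
    C44 = mean(shear, na.rm = TRUE),
    cubic_residual = {
      sp <- c(spread(axial), spread(coup), spread(shear))
      if (all(is.na(sp))) NA_real_ else max(sp, na.rm = TRUE)
    },
    loads = loads, porosity = porosity(grid), resolution = dims[1],
    iterations = iters, relres = relres, materials = materials),
    class = "elasticity_tensor")
}

#' @export
print.elasticity_tensor <- function(x, ...) {
  cat("Effective elasticity tensor (GPa, cubic accessors):\n")
  cat(sprintf("  C11 = %.5g  C12 = %.5g  C44 = %.5g\n", x$C11, x$C12, x$C44))
  cat(sprintf("  porosity %.4f, resolution %d^3, cubic residual %.3g\n",
              x$porosity, x$resolution, x$cubic_residual))
  cat(sprintf("  CG iterations per load: %s\n",
              paste(x$iterations, collapse = ", ")))
  invisible(x)
}

# Per-voxel material ids: 0 void, 1 solid, >= 2 composite row index + 2.
# Composite rows carry one 6x6 stiffness per Gauss point / octant (8 x 36
# values): the rank-1 laminate at the octant's solid fill, oriented along the
# voxel's field gradient. A voxel is composite when any octant is mixed.
build_material_map <- function(grid, materials) {
  dims <- dim(grid$occupancy)
  if (is.null(grid$fill)) {
    id <- ifelse(grid$occupancy, 1L, 0L)
    return(list(id = as.integer(id), comp = matrix(0, 0, 288)))
  }
  oct <- grid$fill_oct
  eps <- 1e-9
  omin <- oct[, , , 1]; omax <- omin
  for (g in 2:8) {
    omin <- pmin(omin, oct[, , , g])
    omax <- pmax(omax, oct[, , , g])
  }
  solid <- omin >= 1 - eps
  void <- omax <= eps
  inter <- which(!solid & !void)
  id <- array(0L, dims)
  id[solid] <- 1L
  Cs <- as.numeric(t(iso_stiffness(materials$E_solid, materials$nu_solid)))
  Cv <- as.numeric(t(iso_stiffness(materials$E_void, materials$nu_void)))
  if (length(inter)) {
    nrm <- interface_normals(grid, inter)
    octm <- matrix(oct, ncol = 8)[inter, , drop = FALSE]
    comp <- matrix(0, length(inter), 288)
    for (q in seq_along(inter)) {
      for (g in 1:8) {
        fg <- octm[q, g]
        cols <- (g - 1) * 36 + 1:36
        comp[q, cols] <-
          if (fg <= eps) Cv
          else if (fg >= 1 - eps) Cs
          else as.numeric(t(composite_stiffness(fg, nrm[q, ], materials)))
      }
    }
    id[inter] <- seq_along(inter) + 1L
  } else comp <- matrix(0, 0, 288)
  list(id = as.integer(id), comp = comp)
}

# interface normals from central differences of the center-sampled field
interface_normals <- function(grid, idx) {
  f <- grid$field
  if (is.null(f)) return(matrix(rep(c(0, 0, 1), each = length(idx)),
                                ncol = 3))
  d <- dim(f)
  ijk <- arrayInd(idx, d)
  wrap <- function(v, n) ((v - 1) %% n) + 1
  comp <- function(ax) {
    up <- ijk; up[, ax] <- wrap(ijk[, ax] + 1, d[ax])
    dn <- ijk; dn[, ax] <- wrap(ijk[, ax] - 1, d[ax])
    f[up] - f[dn]
  }
  cbind(comp(1), comp(2), comp(3))
}

#' Engineering moduli of a cubic effective stiffness
#'
#' Extracts the effective compressive (Young's) and shear moduli from the
#' cubic stiffness constants: `E_e = (C11 - C12)(C11 + 2*C12)/(C11 + C12)` and
#' `G_e = C44`, then normalizes by the solid phase: `E_c = E_e/E_solid`,
#' `G_s = G_e/G_solid`.
#'
#' @param x an `elasticity_tensor`, or a list/named vector with entries
#'   `C11`, `C12`, `C44` (GPa).
#' @param materials a [phase_materials()] object used for the normalization
#'   (taken from `x` when present).
#' @return an object of class `effective_moduli` with `E_e`, `G_e` (GPa) and
#'   the dimensionless `E_c`, `G_s`.
#' @export
effective_moduli <- function(x, materials = NULL) {
  if (inherits(x, "elasticity_tensor")) {
    if (is.null(materials)) materials <- x$materials
    C11 <- x$C11; C12 <- x$C12; C44 <- x$C44
  } else {
    C11 <- x[["C11"]]; C12 <- x[["C12"]]; C44 <- x[["C44"]]
  }
  if (is.null(materials)) materials <- phase_materials()
  if (!is.finite(C11) || !is.finite(C12))
    stop("C11 and C12 are required", call. = FALSE)
  if (C11 + C12 <= 0 || C11 - C12 < 0 || (is.finite(C44) && C44 < 0))
    stop("stiffness is not positive semi-definite (cubic constants C11 = ",
         signif(C11, 6), ", C12 = ", signif(C12, 6), ")", call. = FALSE)
  E_e <- (C11 - C12) * (C11 + 2 * C12) / (C11 + C12)
  G_e <- C44
  structure(list(
    E_e = E_e, G_e = G_e,
    E_c = E_e / materials$E_solid, G_s = G_e / materials$G_solid),
    class = "effective_moduli")
}

#' @export
print.effective_moduli <- function(x, ...) {
  cat(sprintf("E_e = %.5g GPa (E_c = %.5g)\n", x$E_e, x$E_c))
  if (is.finite(x$G_e))
    cat(sprintf("G_e = %.5g GPa (G_s = %.5g)\n", x$G_e, x$G_s))
  invisible(x)
}

#' Mesh-convergence study for the homogenized moduli
#'
#' Recomputes the normalized moduli of a fixed unit-cell geometry on a ladder
#' of voxel resolutions and flags convergence when the successive relative
#' change in both `E_c` and `G_s` falls below `threshold` (default 0.5%, the
#' usual mesh-convergence rule for these models).
#'
#' @param spec a [unit_cell()] specification (its `C` is held fixed).
#' @param resolutions increasing integer vector, length >= 2.
#' @param materials a [phase_materials()] object.
#' @param threshold relative-change convergence threshold.
#' @param ... passed to [homogenize()].
#' @return a `convergence_study`: data frame of per-resolution moduli with a
#'   `converged` attribute.
#' @export
convergence_study <- function(spec, resolutions, materials = phase_materials(),
                              threshold = 0.005, ...) {
  stopifnot(inherits(spec, "unit_cell_spec"))
  resolutions <- as.integer(resolutions)
  if (length(resolutions) < 2 || any(diff(resolutions) <= 0))
    stop("need >= 2 strictly increasing resolutions", call. = FALSE)
  rows <- lapply(resolutions, function(r) {
    g <- voxelize(spec, resolution = r, fill = TRUE)
    m <- effective_moduli(homogenize(g, materials,
                                     loads = c("xx", "xy"), ...))
    data.frame(resolution = r, porosity = porosity(g),
               E_c = m$E_c, G_s = m$G_s)
  })
  df <- do.call(rbind, rows)
  dE <- abs(diff(df$E_c)) / abs(df$E_c[-1])
  dG <- abs(diff(df$G_s)) / abs(df$G_s[-1])
  df$change_E_c <- c(NA, dE)
  df$change_G_s <- c(NA, dG)
  structure(df, converged = any(dE < threshold & dG < threshold),
            threshold = threshold,
            class = c("convergence_study", "data.frame"))
}

#' @export
print.convergence_study <- function(x, ...) {
  cat("Mesh convergence of the homogenized moduli",
      sprintf("(threshold %.2g%%):\n", 100 * attr(x, "threshold")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  cat(if (attr(x, "converged")) "converged\n" else "not converged\n")
  invisible(x)
}
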
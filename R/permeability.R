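#' Fluid model for the permeability analysis
#'
#' Water at room temperature by default: dynamic viscosity 0.001 Pa s,
#' density 998.2 kg/m^3, and a superficial inlet velocity of 0.1 mm/s. At
#' this velocity and pore scale the Reynolds number is of order 1e-4, firmly
#' in the creeping-flow regime, so the steady Stokes equations are solved.
#'
#' @param viscosity dynamic viscosity, Pa s.
#' @param density fluid density, kg/m^3.
#' @param inlet_velocity superficial velocity, mm/s.
#' @return an object of class `fluid_spec`.
#' @export
fluid_spec <- function(viscosity = 0.001, density = 998.2,
                       inlet_velocity = 0.1) {
  if (viscosity <= 0 || density <= 0 || inlet_velocity <= 0)
    stop("all fluid constants must be positive", call. = FALSE)
  structure(list(viscosity = viscosity, density = density,
                 inlet_velocity = inlet_velocity), class = "fluid_spec")
}

#' Stokes flow through the void domain of a scaffold
#'
#' Solves steady incompressible Stokes flow over the void voxels on a
#' staggered (MAC) grid: no-slip on all solid boundaries and on the four
#' lateral walls of the box, flow along `axis`. The solve is driven by a
#' uniform mean pressure gradient with periodic ends (the tiled geometry is
#' periodic along the flow axis); because Stokes flow is linear, the fields
#' are rescaled afterwards so the superficial velocity equals the configured
#' inlet velocity, and the equivalent pressure drop over the sample length is
#' reported. Isolated void pockets and non-percolating branches that do not
#' connect inlet to outlet are excluded before the solve; if no void
#' component spans the sample, the domain is blocked and an error is raised.
#'
#' @param grid a `voxel_grid` (typically a [tile()]d assembly).
#' @param fluid a [fluid_spec()].
#' @param axis flow axis, `"x"`, `"y"` or `"z"`.
#' @param tol relative-residual tolerance of the outer (Schur-complement)
#'   conjugate-gradient iteration.
#' @param maxit_outer,maxit_inner iteration caps for the outer Uzawa-CG and
#'   the inner velocity solves.
#' @param keep_fields if `TRUE`, return the axial velocity and pressure
#'   arrays (rescaled to the inlet velocity).
#' @return an object of class `flow_result`: Darcy permeability `k` (m^2),
#'   volumetric flow `Q` (m^3/s), pressure drop `dP` (Pa), sample length `L`
#'   (m), cross-section `A` (m^2), superficial velocity `ubar` (m/s), void
#'   porosity of the percolating domain, and solver diagnostics.
#' @export
solve_flow <- function(grid, fluid = fluid_spec(), axis = c("z", "x", "y"),
                       tol = 1e-8, maxit_outer = 500, maxit_inner = 50000,
                       keep_fields = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  axis <- match.arg(axis)
  void <- !grid$occupancy
  if (!any(void)) stop("blocked: the cell has no void phase", call. = FALSE)
  perm <- switch(axis, z = 1:3, x = c(3, 2, 1), y = c(1, 3, 2))
  void <- aperm(void, perm)
  d <- dim(void)
  mask <- .cpp_percolating_mask(void, as.integer(d), 2L)
  if (!any(mask))
    stop("blocked: no percolating void path along ", axis, call. = FALSE)

  h <- grid$voxel_size * 1e-3 # m
  mu <- fluid$viscosity
  fz <- 1.0 # Pa/m; permeability is scale-invariant
  sol <- .cpp_stokes(mask, as.integer(d), h, mu, fz, tol,
                     as.integer(maxit_outer), as.integer(maxit_inner),
                     keep_fields)
  if (sol$relres > tol && sol$outer_iterations >= maxit_outer)
    stop(sprintf(
      "Stokes solver did not converge: relative residual %.3g after %d outer iterations",
      sol$relres, sol$outer_iterations), call. = FALSE)

  u_in <- fluid$inlet_velocity * 1e-3 # m/s superficial
  scale <- u_in / sol$ubar
  L <- d[3] * h
  A <- d[1] * d[2] * h^2
  out <- structure(list(
    k = sol$k,
    ubar = u_in,
    Q = u_in * A,
    dP = fz * L * scale,
    L = L, A = A,
    porosity = mean(mask),
    axis = axis,
    outer_iterations = sol$outer_iterations,
    inner_iterations = sol$inner_iterations,
    relres = sol$relres,
    viscosity = mu), class = "flow_result")
  if (keep_fields) {
    out$w <- sol$w * scale
    out$p <- sol$p * scale
  }
  out
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("Darcy permeability k = %.4g m^2\n", x$k))
  cat(sprintf(
    "  Q = %.4g m^3/s, dP = %.4g Pa over L = %.4g m (A = %.4g m^2)\n",
    x$Q, x$dP, x$L, x$A))
  cat(sprintf("  percolating void fraction %.4f; %d outer CG iterations\n",
              x$porosity, x$outer_iterations))
  invisible(x)
}

#' Darcy permeability from flow quantities
#'
#' `k = Q mu L / (A dP)`: the proportionality between superficial velocity
#' and pressure gradient.
#'
#' @param x a `flow_result`, or the flow rate `Q` in m^3/s.
#' @param mu dynamic viscosity, Pa s.
#' @param L sample length, m.
#' @param A cross-sectional area, m^2.
#' @param dP pressure drop, Pa (must be > 0).
#' @return permeability in m^2.
#' @export
darcy_permeability <- function(x, mu, L, A, dP) {
  if (inherits(x, "flow_result")) {
    Q <- x$Q; mu <- x$viscosity; L <- x$L; A <- x$A; dP <- x$dP
  } else Q <- x
  if (dP <= 0) stop("pressure drop must be positive", call. = FALSE)
  Q * mu * L / (A * dP)
}

#' Kozeny-Carman permeability estimate
#'
#' The empirical closed form `k* = phi^3 / (2 s^2)` with `s` the specific
#' surface (inner pore surface area over total sample volume).
#'
#' @param porosity void fraction in [0, 1].
#' @param sv specific surface `s`.
#' @param sv_unit unit of `sv`: `"mm^-1"` (the unit reported by
#'   [measure_morphology()]) or `"m^-1"`.
#' @return permeability estimate in m^2.
#' @export
kozeny_carman <- function(porosity, sv, sv_unit = c("mm^-1", "m^-1")) {
  sv_unit <- match.arg(sv_unit)
  if (any(porosity < 0 | porosity > 1))
    stop("porosity must lie in [0, 1]", call. = FALSE)
  if (any(sv <= 0)) stop("specific surface must be positive", call. = FALSE)
  s <- if (sv_unit == "mm^-1") sv * 1000 else sv
  porosity^3 / (2 * s^2)
}

#' Fit a permeability-porosity relation
#'
#' Least-squares fit of one of three model families: exponential
#' `k = a exp(b phi)` (log-linear), power `k = a phi^b` (log-log) or quadratic
#' `k = a2 phi^2 + a1 phi + a0`. With `family = "auto"` all applicable
#' families are fitted and the one with the highest R^2 on the original k
#' scale is selected (all candidates are kept in the result).
#'
#' @param porosity void fractions (>= 4 points).
#' @param k permeabilities (m^2 or any fixed unit).
#' @param family model family; see Details.
#' @return an object of class `permeability_fit` with `family`,
#'   `coefficients`, `r_squared` and (for `"auto"`) `candidates`.
#' @export
fit_permeability_model <- function(porosity, k,
                                   family = c("auto", "exponential",
                                              "quadratic", "power")) {
  family <- match.arg(family)
  if (length(porosity) != length(k))
    stop("porosity and k lengths differ", call. = FALSE)
  ok <- is.finite(porosity) & is.finite(k)
  porosity <- porosity[ok]; k <- k[ok]
  if (length(k) < 4) stop("need at least 4 points", call. = FALSE)
  if (family %in% c("exponential", "power") && any(k <= 0))
    stop("log-scale families require positive permeabilities", call. = FALSE)

  r2 <- function(pred) {
    sst <- sum((k - mean(k))^2)
    if (sst <= 0) return(1)
    1 - sum((k - pred)^2) / sst
  }
  fit_one <- function(fam) {
    if (fam == "exponential") {
      m <- stats::lm(log(k) ~ porosity)
      cf <- c(a = unname(exp(stats::coef(m)[1])), b = unname(stats::coef(m)[2]))
      pred <- cf["a"] * exp(cf["b"] * porosity)
    } else if (fam == "power") {
      m <- stats::lm(log(k) ~ log(porosity))
      cf <- c(a = unname(exp(stats::coef(m)[1])), b = unname(stats::coef(m)[2]))
      pred <- cf["a"] * porosity^cf["b"]
    } else {
      m <- stats::lm(k ~ porosity + I(porosity^2))
      cf <- c(a2 = unname(stats::coef(m)[3]), a1 = unname(stats::coef(m)[2]),
              a0 = unname(stats::coef(m)[1]))
      pred <- cf["a2"] * porosity^2 + cf["a1"] * porosity + cf["a0"]
    }
    list(family = fam, coefficients = cf, r_squared = r2(pred), fitted = pred)
  }

  if (family != "auto") {
    f <- fit_one(family)
  } else {
    fams <- c("quadratic",
              if (all(k > 0)) c("exponential", "power"))
    cands <- lapply(fams, fit_one)
    names(cands) <- fams
    f <- cands[[which.max(vapply(cands, `[[`, 0, "r_squared"))]]
    f$candidates <- cands
  }
  f$data <- data.frame(porosity = porosity, k = k)
  class(f) <- "permeability_fit"
  f
}

#' @export
print.permeability_fit <- function(x, ...) {
  cf <- x$coefficients
  eq <- switch(x$family,
    exponential = sprintf("k = %.4g exp(%.4g phi)", cf["a"], cf["b"]),
    power = sprintf("k = %.4g phi^%.4g", cf["a"], cf["b"]),
    quadratic = sprintf("k = %.4g phi^2 + %.4g phi + %.4g",
                        cf["a2"], cf["a1"], cf["a0"]))
  cat(eq, sprintf(" (R^2 = %.4f, %s family)\n", x$r_squared, x$family))
  invisible(x)
}

#' @export
coef.permeability_fit <- function(object, ...) object$coefficients

#' @export
predict.permeability_fit <- function(object, porosity, ...) {
  if (missing(porosity)) porosity <- object$data$porosity
  cf <- object$coefficients
  switch(object$family,
    exponential = cf["a"] * exp(cf["b"] * porosity),
    power = cf["a"] * porosity^cf["b"],
    quadratic = cf["a2"] * porosity^2 + cf["a1"] * porosity + cf["a0"])
}

#' @export
residuals.permeability_fit <- function(object, ...) {
  object$data$k - unname(predict(object))
}
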
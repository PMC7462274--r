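#' Two-phase material model for scaffold homogenization
#'
#' The scaffold solid is modelled as Ti-6Al-4V (E = 110 GPa, nu = 0.34) and
#' the void as a very soft filler (E = 1 MPa, nu = 0.45) rather than true
#' emptiness, which keeps the periodic cell problem non-singular when the
#' solid phase does not meet an exterior face; its stiffness contribution is
#' of order 1e-5 of the solid's. Units are GPa throughout.
#'
#' @param E_solid,nu_solid solid-phase Young's modulus (GPa) and Poisson ratio.
#' @param E_void,nu_void void-phase constants (default 1 MPa = 1e-3 GPa, 0.45).
#' @return an object of class `phase_materials` with the derived shear moduli
#'   (`G_solid = E/(2(1+nu))`, approximately 41.05 GPa for the defaults).
#' @export
phase_materials <- function(E_solid = 110, nu_solid = 0.34,
                            E_void = 1e-3, nu_void = 0.45) {
  for (E in c(E_solid, E_void)) if (E <= 0) stop("E must be > 0", call. = FALSE)
  for (nu in c(nu_solid, nu_void))
    if (nu <= -1 || nu >= 0.5) stop("nu must lie in (-1, 0.5)", call. = FALSE)
  structure(list(
    E_solid = E_solid, nu_solid = nu_solid,
    E_void = E_void, nu_void = nu_void,
    G_solid = E_solid / (2 * (1 + nu_solid)),
    G_void = E_void / (2 * (1 + nu_void))), class = "phase_materials")
}

#' @export
print.phase_materials <- function(x, ...) {
  cat(sprintf("Solid: E = %g GPa, nu = %.3f (G = %.4g GPa)\n",
              x$E_solid, x$nu_solid, x$G_solid))
  cat(sprintf("Void : E = %g GPa, nu = %.3f\n", x$E_void, x$nu_void))
  invisible(x)
}

# Voigt order used everywhere: (xx, yy, zz, yz, xz, xy), engineering shear.
iso_stiffness <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

lame_constants <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

voigt_pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))

# expand an engineering-Voigt stiffness to the 9x9 full-tensor matrix
voigt_to_tensor9 <- function(C) {
  V <- matrix(0L, 3, 3)
  for (q in 1:6) {
    V[voigt_pairs[q, 1], voigt_pairs[q, 2]] <- q
    V[voigt_pairs[q, 2], voigt_pairs[q, 1]] <- q
  }
  C9 <- matrix(0, 9, 9)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    C9[i + 3 * (j - 1), k + 3 * (l - 1)] <- C[V[i, j], V[k, l]]
  C9
}

tensor9_to_voigt <- function(C9) {
  C <- matrix(0, 6, 6)
  for (p in 1:6) for (q in 1:6) {
    i <- voigt_pairs[p, 1]; j <- voigt_pairs[p, 2]
    k <- voigt_pairs[q, 1]; l <- voigt_pairs[q, 2]
    C[p, q] <- C9[i + 3 * (j - 1), k + 3 * (l - 1)]
  }
  C
}

# rotate a stiffness (engineering Voigt) by rotation matrix R (local -> global)
rotate_stiffness <- function(C, R) {
  T9 <- kronecker(R, R) # column-major pair flattening: first index fastest
  tensor9_to_voigt(T9 %*% voigt_to_tensor9(C) %*% t(T9))
}

# orthonormal frame whose third column is n
frame_from_normal <- function(n) {
  n <- n / sqrt(sum(n^2))
  e <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
       else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  a1 <- c(n[2] * e[3] - n[3] * e[2],
          n[3] * e[1] - n[1] * e[3],
          n[1] * e[2] - n[2] * e[1])
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(n[2] * a1[3] - n[3] * a1[2],
          n[3] * a1[1] - n[1] * a1[3],
          n[1] * a1[2] - n[2] * a1[1])
  cbind(a1, a2, n)
}

# Backus average of a two-phase rank-1 laminate with layering axis z:
# exact effective stiffness of an isotropic bilayer, transversely isotropic.
backus_vti <- function(f, lam1, mu1, lam2, mu2) {
  avg <- function(q1, q2) f * q1 + (1 - f) * q2
  M1 <- lam1 + 2 * mu1; M2 <- lam2 + 2 * mu2
  iM <- avg(1 / M1, 1 / M2)
  lM <- avg(lam1 / M1, lam2 / M2)
  C33 <- 1 / iM
  C13 <- lM / iM
  C11 <- avg(4 * mu1 * (lam1 + mu1) / M1, 4 * mu2 * (lam2 + mu2) / M2) +
    lM^2 / iM
  C12 <- avg(2 * mu1 * lam1 / M1, 2 * mu2 * lam2 / M2) + lM^2 / iM
  C44 <- 1 / avg(1 / mu1, 1 / mu2)
  C66 <- avg(mu1, mu2)
  C <- matrix(0, 6, 6)
  C[1, 1] <- C[2, 2] <- C11
  C[3, 3] <- C33
  C[1, 2] <- C[2, 1] <- C12
  C[1, 3] <- C[3, 1] <- C[2, 3] <- C[3, 2] <- C13
  C[4, 4] <- C[5, 5] <- C44
  C[6, 6] <- C66
  C
}

# stiffness of an interface voxel: rank-1 laminate of the two phases with
# solid fraction `fill`, oriented along the interface normal
composite_stiffness <- function(fill, normal, materials) {
  s <- lame_constants(materials$E_solid, materials$nu_solid)
  v <- lame_constants(materials$E_void, materials$nu_void)
  Cl <- backus_vti(fill, s$lambda, s$mu, v$lambda, v$mu)
  if (!all(is.finite(normal)) || sum(normal^2) < 1e-30) normal <- c(0, 0, 1)
  rotate_stiffness(Cl, frame_from_normal(normal))
}
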
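# stiffness algebra: Voigt mapping, rotation, Backus laminate

test_that("an isotropic stiffness is invariant under rotation", {
  C <- scaffoldlab:::iso_stiffness(110, 0.34)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  R <- Rx(0.7) %*% Rz(1.1) %*% Rx(-0.4)
  expect_equal(scaffoldlab:::rotate_stiffness(C, R), C, tolerance = 1e-12)
})

test_that("Voigt/tensor round trip is exact", {
  C <- scaffoldlab:::iso_stiffness(3, 0.2)
  C[1, 2] <- C[2, 1] <- C[1, 2] * 1.1 # make it anisotropic
  C9 <- scaffoldlab:::voigt_to_tensor9(C)
  expect_equal(scaffoldlab:::tensor9_to_voigt(C9), C)
})

test_that("Backus laminate reproduces its analytic limits", {
  s <- scaffoldlab:::lame_constants(110, 0.34)
  v <- scaffoldlab:::lame_constants(1e-3, 0.45)
  iso <- scaffoldlab:::iso_stiffness(110, 0.34)
  expect_equal(scaffoldlab:::backus_vti(1, s$lambda, s$mu, v$lambda, v$mu),
               iso, tolerance = 1e-12)
  # zero-Poisson phases: normal stiffness is the harmonic (series) mean and
  # the in-plane shear the arithmetic (parallel) mean
  s0 <- scaffoldlab:::lame_constants(100, 0)
  v0 <- scaffoldlab:::lame_constants(1, 0)
  B <- scaffoldlab:::backus_vti(0.5, s0$lambda, s0$mu, v0$lambda, v0$mu)
  expect_equal(B[3, 3], 1 / (0.5 / 100 + 0.5 / 1))
  expect_equal(B[6, 6], 0.5 * (50 + 0.5))
})

test_that("composite interface stiffness is symmetric positive definite", {
  for (nrm in list(c(0, 0, 1), c(1, 1, 1), c(-2, 0.5, 0.1))) {
    C <- scaffoldlab:::composite_stiffness(0.37, nrm, phase_materials())
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_gt(min(eigen(C, symmetric = TRUE)$values), 0)
  }
})

test_that("rotating the laminate axis equals building it along that axis", {
  s <- scaffoldlab:::lame_constants(110, 0.34)
  v <- scaffoldlab:::lame_constants(1e-3, 0.45)
  Bz <- scaffoldlab:::backus_vti(0.5, s$lambda, s$mu, v$lambda, v$mu)
  Ry <- matrix(c(cos(pi / 2), 0, -sin(pi / 2), 0, 1, 0,
                 sin(pi / 2), 0, cos(pi / 2)), 3)
  Cx <- scaffoldlab:::composite_stiffness(0.5, c(1, 0, 0), phase_materials())
  expect_equal(Cx, scaffoldlab:::rotate_stiffness(Bz, Ry), tolerance = 1e-12)
})

test_that("phase_materials validates and derives the shear moduli", {
  mat <- phase_materials()
  expect_equal(mat$G_solid, 110 / (2 * 1.34))
  expect_equal(round(mat$G_solid, 2), 41.04)
  expect_error(phase_materials(E_solid = -1), "E must be")
  expect_error(phase_materials(nu_void = 0.5), "nu must")
})
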
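# Stokes flow, Darcy post-processing and the Kozeny-Carman estimate

test_that("an open duct reproduces the exact square-duct permeability", {
  fx <- make_fixture("empty", resolution = 64)
  fl <- solve_flow(fx$grid, keep_fields = TRUE)
  a <- 2.5e-3
  k_exact <- scaffoldlab:::square_duct_coefficient() * a^2
  expect_equal(fl$k, k_exact, tolerance = 0.02)
  # mid-plane velocity profile matches plane-Poiseuille shape within 2%:
  # compare the normalized profile against the analytic square-duct series
  w <- fl$w[, 32, 32]
  ref <- profile_square_duct(64)[, 32]
  expect_equal(w / max(w), ref / max(ref), tolerance = 0.02)
})

test_that("a circular channel matches Hagen-Poiseuille within 5%", {
  fx <- make_fixture("circular_channel", resolution = 64, radius = 0.5)
  fl <- solve_flow(fx$grid)
  expect_equal(fl$k, fx$analytic$k, tolerance = 0.05)
  # and the reported pressure drop is consistent with Darcy's law
  expect_equal(darcy_permeability(fl), fl$k, tolerance = 1e-10)
})

test_that("non-percolating domains raise a blocked error", {
  expect_error(solve_flow(make_fixture("full_solid", resolution = 16)$grid),
               "blocked")
  # a channel transverse to the flow axis does not percolate along z
  fx <- make_fixture("circular_channel", resolution = 24, radius = 0.4)
  expect_error(solve_flow(fx$grid, axis = "x"), "blocked")
})

test_that("isolated void pockets are excluded before the solve", {
  fx <- make_fixture("circular_channel", resolution = 24, radius = 0.4)
  occ <- fx$grid$occupancy
  occ[2, 2, 2] <- FALSE # a one-voxel pocket far from the channel
  g <- scaffoldlab:::new_voxel_grid(occ, fx$grid$voxel_size)
  fl <- solve_flow(g)
  expect_equal(fl$porosity, mean(!fx$grid$occupancy), tolerance = 1e-12)
})

test_that("Darcy permeability follows the defining relation", {
  # direct substitution: u = 0.1 mm/s superficial, mu = 1e-3, L = 10 mm,
  # dP = 1 Pa -> k = Q mu L / (A dP) = 1e-9 m^2
  A <- 1e-4
  expect_equal(darcy_permeability(1e-4 * 0.1e-3, mu = 1e-3, L = 0.01,
                                  A = A, dP = 1), 1e-9)
  # doubling the pressure drop at fixed flow halves k
  k1 <- darcy_permeability(1e-8, mu = 1e-3, L = 0.01, A = A, dP = 1)
  k2 <- darcy_permeability(1e-8, mu = 1e-3, L = 0.01, A = A, dP = 2)
  expect_equal(k1 / k2, 2)
  expect_error(darcy_permeability(1e-8, 1e-3, 0.01, A, dP = 0), "positive")
})

test_that("Kozeny-Carman closed form and guards", {
  expect_equal(kozeny_carman(0.5, 1), 0.125 / (2 * 1e6)) # s = 1 mm^-1
  expect_equal(kozeny_carman(0, 1), 0)
  expect_error(kozeny_carman(0.5, 0), "positive")
  expect_error(kozeny_carman(1.2, 1), "porosity")
  expect_equal(kozeny_carman(0.5, 1000, sv_unit = "m^-1"),
               kozeny_carman(0.5, 1))
})

test_that("permeability model fitting recovers exact generating laws", {
  phi <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  fe <- fit_permeability_model(phi, 0.01 * exp(5 * phi), "exponential")
  expect_equal(unname(coef(fe)), c(0.01, 5), tolerance = 1e-10)
  expect_equal(fe$r_squared, 1, tolerance = 1e-10)
  fp <- fit_permeability_model(phi, 1.25 * phi^4.2, "power")
  expect_equal(unname(coef(fp)), c(1.25, 4.2), tolerance = 1e-10)
  fq <- fit_permeability_model(phi, 0.9 * phi^2 - 0.5 * phi + 0.1, "quadratic")
  expect_equal(unname(coef(fq)), c(0.9, -0.5, 0.1), tolerance = 1e-10)
  fa <- fit_permeability_model(phi, 0.01 * exp(5 * phi), "auto")
  expect_equal(fa$family, "exponential")
  expect_named(fa$candidates, c("quadratic", "exponential", "power"))
  expect_error(fit_permeability_model(phi, c(-1, 1, 2, 3, 4), "exponential"),
               "positive")
  expect_error(fit_permeability_model(phi[1:3], phi[1:3], "quadratic"),
               "at least 4")
})

test_that("flow is insensitive to the 0.1 mm/s scaling convention", {
  fx <- make_fixture("circular_channel", resolution = 32, radius = 0.5)
  f1 <- solve_flow(fx$grid, fluid_spec(inlet_velocity = 0.1))
  f2 <- solve_flow(fx$grid, fluid_spec(inlet_velocity = 0.2))
  expect_equal(f1$k, f2$k, tolerance = 1e-12)  # permeability is intrinsic
  expect_equal(f2$Q / f1$Q, 2, tolerance = 1e-12)
  expect_equal(f2$dP / f1$dP, 2, tolerance = 1e-12)
})
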
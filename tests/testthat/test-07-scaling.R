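# Gibson-Ashby law, deformation-mode classification, shear-compression line

test_that("noise-free Gibson-Ashby data is recovered to three decimals", {
  rho <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  f <- fit_gibson_ashby(rho, 0.9 * rho^2 + 0.001)
  expect_equal(f$C1, 0.9, tolerance = 1e-3)
  expect_equal(f$n, 2, tolerance = 1e-3)
  expect_equal(f$E0, 0.001, tolerance = 1e-3)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)
  expect_equal(f$mode, "bending")
  # both objectives recover exact data, including a negative offset
  for (w in c("relative", "absolute")) {
    g <- fit_gibson_ashby(rho, 0.95 * rho^0.863 - 0.21, weighting = w)
    expect_equal(g$n, 0.863, tolerance = 1e-3)
    expect_equal(g$mode, "stretching")
  }
})

test_that("gibson_ashby methods behave like a model object", {
  rho <- c(0.3, 0.45, 0.55, 0.7)
  f <- fit_gibson_ashby(rho, 0.8 * rho^1.5)
  expect_named(coef(f), c("C1", "n", "E0"))
  expect_equal(unname(predict(f, 0.5)), 0.8 * 0.5^1.5, tolerance = 1e-6)
  expect_lt(max(abs(residuals(f))), 1e-8)
  expect_output(print(f), "rho")
})

test_that("fit errors are informative", {
  expect_error(fit_gibson_ashby(c(0.3, 0.5, 0.7), c(1, 2, 3) / 10),
               "at least 4")
  expect_error(fit_gibson_ashby(c(0.3, 0.5, 0.7, 1.2), rep(0.1, 4)),
               "relative densities")
  expect_error(fit_gibson_ashby(c(0.3, 0.4, 0.5, 0.6), c(-1, 1, 2, 3)),
               "positive")
})

test_that("the deformation-mode threshold sits at n = 1.7", {
  expect_equal(classify_mode(2.081), "bending")
  expect_equal(classify_mode(1.474), "stretching")
  expect_equal(classify_mode(1.7), "bending") # boundary belongs to bending
  expect_equal(classify_mode(c(0.9, 2.3)), c("stretching", "bending"))
  expect_error(classify_mode(-1), "positive")
})

test_that("the shear-compression regression is exact on linear data", {
  E <- c(0.05, 0.1, 0.2, 0.3)
  f <- suppressWarnings(fit_linear_relation(E, 2 * E + 0.1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0.1)
  expect_equal(f$r_squared, 1)
  expect_equal(unname(predict(f, 0.5)), 1.1)
  expect_error(fit_linear_relation(E[1:2], E[1:2]), "at least 3")
  expect_error(fit_linear_relation(rep(0.2, 4), E), "variance")
})
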
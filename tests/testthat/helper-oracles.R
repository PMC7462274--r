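# analytic Poiseuille velocity field of a square duct, evaluated at the
# n x n staggered-grid cell centers and normalized to a peak of one
profile_square_duct <- function(n, nterms = 99) {
  a <- 1
  xc <- (seq_len(n) - 0.5) / n * a
  w <- matrix(0, n, n)
  for (m in seq(1, nterms, by = 2)) {
    shape <- 1 - cosh(m * pi * (xc - a / 2) / a) / cosh(m * pi / 2)
    w <- w + (1 / m^3) * outer(shape, sin(m * pi * xc / a))
  }
  w / max(w)
}
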
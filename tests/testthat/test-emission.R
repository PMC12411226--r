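mk_G <- function(lam, val = 1) {
  g <- data.frame(lambda_nm = lam, G = rep(val, length(lam)))
  attr(g, "scale") <- 1
  g
}

test_that("liet_spectrum is the pointwise product with strict grids", {
  lam <- seq(600, 700, by = 10)
  H <- spectral_electronic_contribution(fix_bands, 2.3, lam)
  I <- liet_spectrum(H, mk_G(lam))
  expect_equal(I$intensity, H$H)          # G == 1 -> I proportional to H
  expect_error(liet_spectrum(H, mk_G(lam + 1)), "grids")
})

test_that("the cut-off dominates the product regardless of G", {
  lam <- c(500, 520, 900)                  # cut-off for 2.3 V: 539 nm
  H <- spectral_electronic_contribution(fix_bands, 2.3, lam)
  I <- liet_spectrum(H, mk_G(lam, 100))
  expect_lt(I$intensity[1] / I$intensity[3], 1e-3)
  expect_lt(I$intensity[2] / I$intensity[3], 0.05)
})

test_that("separability: bias ratios are independent of the photonic
           model", {
  lam <- seq(560, 900, by = 20)
  H1 <- spectral_electronic_contribution(fix_bands, 1.9, lam,
                                         normalize = FALSE)
  H2 <- spectral_electronic_contribution(fix_bands, 2.3, lam,
                                         normalize = FALSE)
  set.seed(7)
  Ga <- mk_G(lam, 1); Ga$G <- runif(length(lam), 0.2, 2)
  Gb <- mk_G(lam, 1); Gb$G <- runif(length(lam), 0.2, 2)
  Ia1 <- liet_spectrum(H1, Ga); Ia2 <- liet_spectrum(H2, Ga)
  Ib1 <- liet_spectrum(H1, Gb); Ib2 <- liet_spectrum(H2, Gb)
  expect_equal(Ia2$intensity / Ia1$intensity,
               Ib2$intensity / Ib1$intensity, tolerance = 1e-12)
  expect_equal(Ia2$intensity / Ia1$intensity, H2$H / H1$H,
               tolerance = 1e-12)
})

test_that("find_peak interpolates and flags edges", {
  lam <- seq(600, 700, by = 5)
  y <- exp(-(lam - 643)^2 / 400)
  pk <- find_peak(lam, y, c(600, 700))
  expect_lt(abs(pk$lambda - 643), 0.5)     # sub-grid accuracy
  expect_false(pk$at_edge)
  expect_warning(pk2 <- find_peak(lam, lam, c(600, 700)), "edge")
  expect_true(pk2$at_edge)
  expect_error(find_peak(lam, y, c(600, 604)), "fewer")
})

test_that("bias family: onset follows the quantum cut-off and intensity
           grows", {
  lam <- seq(540, 950, by = 10)
  fam <- h_vs_bias(fix_bands, c(1.5, 1.9, 2.3), lam)
  # onset: for 1.5 V the cut-off is 827 nm; H below must be tiny
  h15 <- fam[["V1.5"]]
  expect_lt(max(h15$H[lam < 780]), 0.02 * max(h15$H))
  # intensity grows with bias for any fixed non-negative G
  G <- mk_G(lam); G$G <- 0.5 + 0.5 * sin(lam / 40)^2
  ints <- vapply(fam, function(h) sum(liet_spectrum(h, G)$intensity),
                 numeric(1))
  expect_true(all(diff(ints) > 0))
})

test_that("angle-resolved emission map respects grid and k_par bookkeeping", {
  dev <- fix_char$device
  lam <- seq(600, 1000, by = 100)
  th <- c(0.1, 0.3, 0.5)
  m <- photonic_map(dev, lam, th, n_dipoles = 5, N = 11)
  em <- angle_resolved_emission(dev, fix_bands, 2.3, lam, th, map = m)
  expect_equal(dim(em$I), c(length(lam), length(th)))
  expect_true(all(em$I >= 0))
  # k_par = (2 pi / lambda) * n * sin(theta), n = 1 on the air side
  expect_equal(em$k_par_um[2, 3],
               2 * pi / (lam[2] / 1000) * sin(th[3]), tolerance = 1e-12)
  # the product vanishes beyond the cut-off row-wise
  b1 <- electronic_bands(T_K = 1)
  em0 <- angle_resolved_emission(dev, b1, 1.2, lam, th, map = m)
  expect_true(all(em0$I[lam < 1033, ] < 1e-9 * max(m$G)))
})
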
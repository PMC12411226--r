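test_that("reciprocity equals the direct dipole oracle on the planar
           stack (1%)", {
  dev <- fix_char$device
  th <- seq(0.05, 0.9, length.out = 9)
  for (side in c("superstrate", "substrate")) {
    for (lam in c(650, 900)) {
      gd <- dipole_farfield_direct(dev, lam, th, from = side)
      gr <- dipole_farfield_reciprocal(dev, lam, th, from = side)
      sc <- sum(Conj(gr) * gd) / sum(Mod(gr)^2)  # one global constant
      expect_lt(max(Mod(gd - sc * gr)) / max(Mod(gd)), 0.01,
                label = paste(side, lam))
    }
  }
})

test_that("s-polarized far-field requests are rejected", {
  expect_error(farfield_amplitude(fix_char$device, 650, 0.3, pol = "s"),
               "rejected")
})

test_that("Eq.-3 combination rules: incoherent l-sum, coherent amplitudes", {
  dev <- fix_char$device
  g <- farfield_amplitude(dev, 650, 0.3, x_nm = c(-20, 0, 20), N = 11)
  # single dipole: curly_G = |g|^2
  expect_equal(angle_resolved_photonic(dev, 650, 0.3, x_nm = 0, N = 11),
               Mod(g[2])^2)
  # M identical l-groups add incoherently: repeating a position M times
  expect_equal(angle_resolved_photonic(dev, 650, 0.3, x_nm = rep(0, 4),
                                       N = 11),
               4 * Mod(g[2])^2, tolerance = 1e-12)
  # n in-phase dipoles in one coherent group: |n g|^2 = n^2 |g|^2
  expect_equal(Mod(3 * g[2])^2, 9 * Mod(g[2])^2)
  expect_error(angle_resolved_photonic(dev, 650, 0.3, x_nm = numeric(0)),
               "non-empty")
})

test_that("mirror symmetry: curly_G(theta) = curly_G(-theta)", {
  dev <- fix_char$device
  expect_equal(gap_intensity(dev, 700, 0.35), gap_intensity(dev, 700, -0.35),
               tolerance = 1e-10)
})

test_that("the dispersive anomaly follows the grating-equation slope", {
  # lattice-mode locus: lambda = P (n_spp + sin(theta)); between two
  # wavelengths the anomaly angle must shift by
  # sin(theta2) - sin(theta1) = (lambda2 - lambda1) / P
  dev <- fix_char$device
  th_grid <- seq(20, 50, by = 1) * pi / 180
  peak_th <- function(lam) {
    v <- vapply(th_grid, function(t) gap_intensity(dev, lam, t, N = 21),
                numeric(1))
    th_grid[which.max(v)]
  }
  t1 <- peak_th(625); t2 <- peak_th(675)
  d_sin_solver <- sin(t2) - sin(t1)
  d_sin_grating <- (675 - 625) / dev$period_x
  # within the angular grid spacing around the anomaly angles
  grid_tol <- abs(cos(t1)) * (2 * pi / 180) + abs(cos(t2)) * (2 * pi / 180)
  expect_lt(abs(d_sin_solver - d_sin_grating), grid_tol)
  # and the implied mode index slightly exceeds the light line
  n_spp <- 625 / dev$period_x - sin(t1)
  expect_gt(n_spp, 0.98)
  expect_lt(n_spp, 1.2)
})

test_that("G is monotone in NA (nested angular domains)", {
  dev <- fix_char$device
  lam <- c(600, 700, 900)
  g08 <- photonic_contribution(dev, lam, NA_obj = 0.8, n_theta = 9,
                               n_dipoles = 7, N = 15, normalize = FALSE)
  g03 <- photonic_contribution(dev, lam, NA_obj = 0.3, n_theta = 9,
                               n_dipoles = 7, N = 15, normalize = FALSE)
  expect_true(all(g08$G >= g03$G))
  expect_error(photonic_contribution(dev, lam, NA_obj = 1.5), "NA")
})

test_that("grating G is enhanced over the planar reference in the
           lattice band", {
  dev <- fix_char$device
  lam <- seq(560, 740, by = 60)
  gg <- photonic_contribution(dev, lam, NA_obj = 0.8, n_theta = 9,
                              n_dipoles = 7, N = 15, normalize = FALSE)
  gp <- photonic_contribution_planar(dev, lam, NA_obj = 0.8, n_theta = 9)
  expect_true(all(gg$G > gp$G))
})

test_that("overlayer redshifts the lattice-band edge of G", {
  # adding a 45 nm n = 1.49 layer moves spectral weight to longer
  # wavelengths: the long-wavelength side of the band gains relative to
  # the short side
  dev <- fix_char$device
  dev_p <- dev
  dev_p$overlayer <- list(material = "PMMA", thickness_nm = 45)
  lam <- c(580, 740)
  gb <- photonic_contribution(dev, lam, NA_obj = 0.8, n_theta = 9,
                              n_dipoles = 7, N = 21, normalize = FALSE)
  gp <- photonic_contribution(dev_p, lam, NA_obj = 0.8, n_theta = 9,
                              n_dipoles = 7, N = 21, normalize = FALSE)
  expect_gt(gp$G[2] / gp$G[1], gb$G[2] / gb$G[1])
})

test_that("quadrature warning for coarse angular grids", {
  expect_warning(
    photonic_contribution(fix_char$device, 650, NA_obj = 0.8, n_theta = 5,
                          n_dipoles = 3, N = 11),
    "2 degrees")
})
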
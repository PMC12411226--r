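test_that("fermi_occupation: symmetry, asymptotics, stability", {
  expect_equal(fermi_occupation(0, 0, 300), 0.5)
  kT <- 8.617333262e-5 * 300
  expect_lt(fermi_occupation(50 * kT, 0, 300), 1e-21)
  expect_true(is.finite(fermi_occupation(600 * kT, 0, 300)))
  # particle-hole symmetry at x = 0.1 eV
  expect_equal(fermi_occupation(0.1, 0, 300) + fermi_occupation(-0.1, 0, 300),
               1, tolerance = 1e-12)
  expect_error(fermi_occupation(0, 0, -1), "T")
})

test_that("quantum cut-off is exact in the T -> 0 limit", {
  b1 <- electronic_bands(T_K = 1)
  # cutoff for 2.0 V is 619.9 nm; below-cutoff wavelengths must vanish
  h <- spectral_electronic_contribution(b1, 2.0, c(580, 610, 640, 700))
  expect_equal(h$H[1], 0, tolerance = 1e-6)
  expect_equal(h$H[2], 0, tolerance = 1e-6)
  expect_gt(h$H[3], 1e-4)
  expect_gt(h$H[4], h$H[3])
})

test_that("single-integral H matches the brute-force 2D oracle to 0.5%", {
  pts <- list(c(2.3, 1.55), c(2.3, 2.10), c(2.0, 1.90), c(1.7, 1.20),
              c(1.5, 1.45))
  for (pt in pts) {
    fast <- spectral_electronic_contribution(fix_bands, pt[1],
                                             nm_from_ev(pt[2]),
                                             normalize = FALSE)$H
    slow <- h_bruteforce_2d(fix_bands, pt[1], pt[2])
    expect_rel(fast, slow, 0.005)
  }
})

test_that("H increases towards longer wavelengths and with bias", {
  lam <- seq(550, 950, by = 25)
  h23 <- spectral_electronic_contribution(fix_bands, 2.3, lam,
                                          normalize = FALSE)
  expect_gt(h23$H[lam == 900], h23$H[lam == 600])
  fam <- h_vs_bias(fix_bands, seq(1.5, 2.3, by = 0.2), lam)
  # shared normalization: family maximum is 1
  expect_equal(max(vapply(fam, function(h) max(h$H), numeric(1))), 1)
  # monotone in bias at every wavelength below all cut-offs (> 827 nm)
  sub <- lam > 840
  for (i in seq_len(length(fam) - 1)) {
    expect_true(all(fam[[i + 1]]$H[sub] >= fam[[i]]$H[sub] - 1e-12))
  }
  # 700 nm: 2.3 V beats 1.5 V (the latter is beyond cut-off there)
  expect_gt(fam$V2.3$H[lam == 700], fam$V1.5$H[lam == 700])
})

test_that("sub-cut-off bias gives H ~ 0 over the visible", {
  # 1.2 V cut-off sits at 1033 nm; more than ~4 kBT inside (<= 900 nm)
  # only thermal-tail remnants survive
  h <- spectral_electronic_contribution(fix_bands, 1.2,
                                        seq(500, 900, by = 50),
                                        normalize = FALSE)
  ref <- spectral_electronic_contribution(fix_bands, 1.2, 1100,
                                          normalize = FALSE)
  expect_true(all(h$H < 5e-3 * ref$H))
})

test_that("cut-off edge smearing matches the double-Fermi kernel width
           and scales with T", {
  # near the edge (constant DOS) H(D) -> C * D / (1 - exp(-D/kBT)) with
  # D = e Vb - hbar w; the 10-90 width of dH/dD is a universal multiple
  # of kBT (~6.2), computed here from the closed form as the oracle
  x <- seq(-12, 12, by = 0.01)
  gx <- x / (1 - exp(-x)); gx[abs(x) < 1e-12] <- 1
  dg <- diff(gx) / diff(x)
  xm <- (x[-1] + x[-length(x)]) / 2
  # dg rises monotonically from 0 to 1; 10-90 transition span
  w_univ <- min(xm[dg >= 0.90]) - min(xm[dg >= 0.10])
  vb <- 2.0
  width_at <- function(T_K) {
    b <- electronic_bands(T_K = T_K)
    kT <- 8.617333262e-5 * T_K
    e <- seq(vb - 8 * kT, vb + 8 * kT, by = kT / 5)
    h <- vapply(e, function(z)
      spectral_electronic_contribution(b, vb, nm_from_ev(z),
                                       normalize = FALSE)$H, numeric(1))
    d <- -diff(h) / diff(e)
    em <- (e[-1] + e[-length(e)]) / 2
    dn <- d / mean(d[em < vb - 4 * kT])
    max(em[dn >= 0.10]) - max(em[dn >= 0.90])
  }
  kT300 <- 8.617333262e-5 * 300
  w300 <- width_at(300)
  expect_rel(w300 / kT300, w_univ, 0.1)   # matches the kernel oracle
  expect_rel(width_at(600) / w300, 2, 0.1)  # grows linearly with T
})

test_that("argument and resolution guards", {
  expect_error(spectral_electronic_contribution(fix_bands, -1, 650), "V_b")
  expect_error(h_vs_bias(fix_bands, numeric(0), 650), "empty")
  expect_error(h_vs_bias(fix_bands, c(2, 1.5), 650), "sorted")
  expect_warning(
    spectral_electronic_contribution(fix_bands, 2, 650, dE_ev = 0.1),
    "coarser")
})
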
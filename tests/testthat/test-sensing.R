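mk_spec <- function(lam, y) data.frame(lambda_nm = lam, intensity = y)

test_that("differential band signal: identity, scaling, guards", {
  lam <- seq(600, 720, by = 2)
  base <- mk_spec(lam, 1 + 0.3 * sin(lam / 15))
  expect_equal(differential_band_signal(base, base), 0)
  twice <- base; twice$intensity <- 2 * base$intensity
  expect_equal(differential_band_signal(twice, base), 1, tolerance = 1e-12)
  expect_error(differential_band_signal(base, mk_spec(lam + 1, lam)),
               "grid")
  expect_error(differential_band_signal(base, base, band = c(100, 200)),
               "band")
  zero <- base; zero$intensity <- 0 * base$intensity
  expect_error(differential_band_signal(base, zero), "degenerate")
})

test_that("peak fold change: identity, scale invariance, edge warning", {
  lam <- seq(550, 750, by = 2)
  a <- mk_spec(lam, exp(-(lam - 655)^2 / 800))
  expect_equal(peak_fold_change(a, a), 1)
  b <- a; b$intensity <- 2.13 * a$intensity
  expect_equal(peak_fold_change(b, a), 2.13, tolerance = 1e-9)
  expect_equal(peak_fold_change(b, a),
               peak_fold_change(mk_spec(lam, 2 * b$intensity),
                                mk_spec(lam, 2 * a$intensity)),
               tolerance = 1e-12)
  ramp <- mk_spec(lam, lam)
  expect_warning(peak_fold_change(ramp, a), "edge")
})

test_that("LOD: exact linear interpolation case and monotonicity in
           noise", {
  sigma <- 0.02
  m <- c(3, 9, 27)
  resp <- data.frame(mass_pg = m, response_mean = m * (3 * sigma) / 9)
  lod <- limit_of_detection(resp, sigma)
  expect_equal(lod$lod_pg, 9, tolerance = 1e-12)
  expect_equal(lod$bracket, c(3, 9))
  expect_false(lod$extrapolated)
  lod2 <- limit_of_detection(resp, sigma / 2)
  expect_lt(lod2$lod_pg, lod$lod_pg)
})

test_that("LOD: isotonic fallback, extrapolation flag, no-crossing", {
  resp <- data.frame(mass_pg = c(5, 10, 20, 40),
                     response_mean = c(0.01, 0.05, 0.04, 0.20))
  expect_warning(lod <- limit_of_detection(resp, 0.02), "isotonic")
  expect_true(lod$isotonic_used)
  expect_true(is.finite(lod$lod_pg))
  # all responses already above threshold -> extrapolated below range
  hi <- data.frame(mass_pg = c(5, 10, 20), response_mean = c(0.5, 0.8, 1))
  lod3 <- limit_of_detection(hi, 0.01)
  expect_true(lod3$extrapolated)
  expect_lte(lod3$lod_pg, 5)
  # never reaching threshold -> NA
  lo <- data.frame(mass_pg = c(5, 10, 20),
                   response_mean = c(0.001, 0.002, 0.003))
  lod4 <- limit_of_detection(lo, 1)
  expect_true(is.na(lod4$lod_pg))
})

test_that("mass-to-thickness mapping follows mass/(density*area)", {
  # 50 pg over 50 x 50 um^2 at 1.42 g/cm3 -> ~14.08 nm
  expect_equal(mass_to_thickness(50), 50e-12 / (1.42 * 2.5e-5) * 1e7,
               tolerance = 1e-12)
  expect_equal(mass_to_thickness(0), 0)
  # halving the area doubles the thickness
  expect_equal(mass_to_thickness(10, area_um2 = 1250),
               2 * mass_to_thickness(10), tolerance = 1e-12)
})

test_that("simulated response is monotone in analyte thickness
           (noiseless)", {
  dev <- fix_sens$device
  lam <- seq(580, 740, by = 5)
  G <- function(d) photonic_contribution(d, lam, NA_obj = 0.3, n_theta = 5,
                                         n_dipoles = 7, N = 15,
                                         normalize = FALSE)
  H <- spectral_electronic_contribution(fix_bands, 2.8, lam,
                                        normalize = FALSE)
  bare <- mk_spec(lam, H$H * G(dev)$G)
  resp <- vapply(c(3, 8, 14), function(t) {
    d2 <- dev
    d2$overlayer <- list(material = "analyte", thickness_nm = t)
    differential_band_signal(mk_spec(lam, H$H * G(d2)$G), bare)
  }, numeric(1))
  expect_true(all(resp > 0))
  expect_true(all(diff(resp) > 0))
})
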
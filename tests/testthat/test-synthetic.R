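model_spec <- data.frame(lambda_nm = seq(600, 700, by = 0.25),
                         intensity = 1 + 0.5 * sin(seq(600, 700,
                                                       by = 0.25) / 10))

test_that("zero-scale noise returns the model exactly; seeds reproduce", {
  nz0 <- noise_model("poisson_counts", 0, seed = 1)
  s0 <- synth_spectrum(model_spec, nz0)
  expect_equal(s0$raw, model_spec$intensity)
  nz <- noise_model("poisson_counts", 500, seed = 11)
  s1 <- synth_spectrum(model_spec, nz)
  s2 <- synth_spectrum(model_spec, nz)
  expect_identical(s1$raw, s2$raw)
  s3 <- synth_spectrum(model_spec, noise_model("poisson_counts", 500,
                                               seed = 12))
  expect_false(identical(s1$raw, s3$raw))
  expect_error(noise_model("poisson_counts", 10), "seed")
})

test_that("smoothing uses the 2.5 nm / 10-point convention", {
  nz <- noise_model("poisson_counts", 200, seed = 3)
  s <- synth_spectrum(model_spec, nz)             # grid step 0.25 nm
  expect_equal(attr(s, "manifest")$params$n_points, 10)
  # smoothed trace has lower residual variance than the raw one
  expect_lt(stats::var(s$smoothed - model_spec$intensity),
            stats::var(s$raw - model_spec$intensity))
  coarse <- data.frame(lambda_nm = seq(600, 700, by = 2), intensity = 1)
  expect_error(synth_spectrum(coarse, nz), "2 grid steps")
})

test_that("Poisson replicate mean converges to the model (LLN, 1%)", {
  lam <- seq(620, 640, by = 1)
  model <- data.frame(lambda_nm = lam, intensity = seq(1, 3, length.out =
                                                         length(lam)))
  scale <- 150   # expected counts >= 150 everywhere
  acc <- 0
  for (k in seq_len(500)) {
    nz <- noise_model("poisson_counts", scale, seed = 10000 + k)
    acc <- acc + synth_spectrum(model, nz)$raw
  }
  expect_true(all(abs(acc / 500 - model$intensity) / model$intensity
                  < 0.01))
})

test_that("synthetic I-V: exact at zero noise, reproducible, refittable", {
  p <- barrier_params(2.62, 3.2)
  V <- seq(0.1, 2.4, length.out = 60)
  iv0 <- synth_iv(p, V, noise_model("multiplicative_gaussian", 0,
                                    seed = 5))
  expect_equal(iv0$J, simmons_J(V, p))
  iv1 <- synth_iv(p, V, noise_model("multiplicative_gaussian", 0.01,
                                    seed = 5))
  iv2 <- synth_iv(p, V, noise_model("multiplicative_gaussian", 0.01,
                                    seed = 5))
  expect_identical(iv1$J, iv2$J)
  fit <- fit_simmons(iv1)
  expect_rel(fit$params$phi_ev, 2.62, 0.05)
  expect_rel(fit$params$ds_nm, 3.2, 0.05)
  expect_error(synth_iv(p, c(0.5, 0.4), iv1), "ascending")
  expect_false(is.null(attr(iv1, "manifest")$noise$seed))
})

test_that("emission images: CV behaviour and defect geometry", {
  nz0 <- noise_model("poisson_counts", 0, seed = 9)
  img0 <- synth_emission_image(100, c(64, 64), noise = nz0)
  expect_equal(img0$cv, 0)
  defect <- data.frame(row = 20, width = 3, attenuation = 0.5)
  img1 <- synth_emission_image(100, c(64, 64), defects = defect,
                               noise = nz0)
  expect_gt(img1$cv, img0$cv)
  expect_equal(img1$cv_excluding_defects, 0)
  expect_error(synth_emission_image(100, c(64, 64),
                                    defects = data.frame(row = 63,
                                                         width = 5,
                                                         attenuation = 0.5),
                                    noise = nz0),
               "outside")
  expect_error(synth_emission_image(100, c(32, 64), noise = nz0), "64")
  # CV of a pure-noise image matches the analytic Poisson CV within 5%:
  # counts ~ Poisson(mu) with mu = 80 -> CV = 1/sqrt(mu)
  nzp <- noise_model("poisson_counts", 0.8, seed = 21)
  imgp <- synth_emission_image(100, c(96, 96), noise = nzp)
  expect_rel(imgp$cv, 1 / sqrt(80), 0.05)
})

test_that("PGM writer emits valid plain-text P2", {
  f <- tempfile(fileext = ".pgm")
  write_pgm(matrix(c(0, 1, 2, 3), 2, 2), f, maxval = 9)
  ln <- readLines(f)
  expect_equal(ln[1], "P2")
  expect_equal(ln[2], "2 2")
  expect_equal(ln[3], "9")
})

test_that("dose series feeds limit_of_detection without transformation", {
  # solver-light check of the schema contract and determinism
  dev <- fix_sens$device
  masses <- c(10, 30, 50)
  nz <- noise_model("poisson_counts", 200, seed = 77)
  ser1 <- analyte_dose_series(masses, dev, fix_bands, replicates = 2,
                              lambda_nm = seq(590, 730, by = 5),
                              N = 11, n_theta = 5, n_dipoles = 5,
                              noise = nz)
  expect_named(ser1$responses,
               c("mass_pg", "thickness_nm", "response_mean", "response_sd",
                 "n_replicates"))
  lod <- limit_of_detection(ser1$responses, ser1$noise_level)
  expect_true(is.finite(lod$threshold))
  ser2 <- analyte_dose_series(masses, dev, fix_bands, replicates = 2,
                              lambda_nm = seq(590, 730, by = 5),
                              N = 11, n_theta = 5, n_dipoles = 5,
                              noise = nz)
  expect_identical(ser1$responses, ser2$responses)
  expect_error(analyte_dose_series(c(-1, 5), dev, fix_bands, noise = nz),
               "positive")
  expect_error(analyte_dose_series(5000, dev, fix_bands, noise = nz),
               "range")
})
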
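## Seeded synthetic measurements: noisy spectra with the 10-point / 2.5 nm
## smoothing convention, tunnelling I-V curves, emission images with
## line-defect discontinuities, and analyte dose series. Everything is
## reproducible from (parameters, seed) via R's Mersenne-Twister generator;
## each generator attaches a manifest recording both.

#' Noise model for synthetic measurements
#'
#' @param kind \code{"poisson_counts"} (scale = expected counts per unit of
#'   model intensity) or \code{"multiplicative_gaussian"} (scale = relative
#'   s.d.).
#' @param scale positive scale parameter; 0 is allowed and means "no
#'   noise".
#' @param seed mandatory integer seed.
#' @return object of class \code{liet_noise}.
#' @export
noise_model <- function(kind = c("poisson_counts",
                                 "multiplicative_gaussian"),
                        scale, seed) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(scale >= 0)
  structure(list(kind = kind, scale = scale, seed = as.integer(seed)),
            class = "liet_noise")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.apply_noise <- function(values, noise) {
  if (noise$scale == 0) return(values)
  .with_seed(noise$seed, switch(noise$kind,
    poisson_counts = stats::rpois(length(values),
                                  pmax(values * noise$scale, 0)) /
      noise$scale,
    multiplicative_gaussian = values *
      (1 + noise$scale * stats::rnorm(length(values)))
  ))
}

.manifest <- function(generator, params, noise = NULL) {
  list(generator = generator, params = params,
       noise = if (is.null(noise)) NULL else unclass(noise),
       package_version = as.character(utils::packageVersion("lietsim")),
       rng = "Mersenne-Twister")
}

#' Synthetic noisy spectrum with smoothing
#'
#' Applies the noise model to a model spectrum and returns the raw noisy
#' trace together with a moving-average smoothed trace (default window
#' 2.5 nm, i.e. 10 points on a 0.25 nm grid).
#'
#' @param model data.frame(lambda_nm, intensity): the noiseless spectrum.
#' @param noise a [noise_model()].
#' @param smooth_window_nm smoothing window, nm; must span >= 2 grid steps.
#' @return data.frame(lambda_nm, raw, smoothed) with attribute
#'   \code{manifest}.
#' @export
synth_spectrum <- function(model, noise, smooth_window_nm = 2.5) {
  lam <- model$lambda_nm
  step <- stats::median(diff(lam))
  npts <- max(round(smooth_window_nm / step), 1)
  if (npts < 2)
    stop("smoothing window (", smooth_window_nm,
         " nm) spans fewer than 2 grid steps (step = ", signif(step, 3),
         " nm)")
  raw <- .apply_noise(model$intensity, noise)
  kern <- rep(1 / npts, npts)
  sm <- stats::filter(raw, kern, sides = 2)
  # fill the edges with shrinking one-sided windows
  sm <- as.numeric(sm)
  half <- floor(npts / 2)
  n <- length(raw)
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(raw[lo:hi])
  }
  out <- data.frame(lambda_nm = lam, raw = raw, smoothed = sm)
  attr(out, "manifest") <- .manifest("synth_spectrum",
                                     list(smooth_window_nm = smooth_window_nm,
                                          n_points = npts), noise)
  out
}

#' Synthetic tunnelling I-V curve
#'
#' @param p a [barrier_params()].
#' @param V positive ascending bias grid (V).
#' @param noise a [noise_model()] (typically multiplicative_gaussian).
#' @return object of class \code{iv_curve}: data.frame(V, J) with
#'   attribute \code{manifest}.
#' @export
synth_iv <- function(p, V, noise) {
  if (any(V <= 0) || is.unsorted(V, strictly = TRUE))
    stop("V grid must be positive and strictly ascending")
  J <- .apply_noise(simmons_J(V, p), noise)
  out <- data.frame(V = V, J = J)
  attr(out, "manifest") <- .manifest("synth_iv", unclass(p), noise)
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Synthetic emission image with optional line defects
#'
#' Emulates wide-field electroluminescence maps: a uniform base intensity,
#' optional dark horizontal defect lines (emission discontinuities across
#' wires), and counting or multiplicative noise. The uniformity metric is
#' the coefficient of variation (CV), computed with or without the defect
#' rows.
#'
#' @param base_intensity mean intensity (model units).
#' @param shape c(rows, cols), each >= 64.
#' @param defects data.frame(row, width, attenuation) or NULL; attenuation
#'   in [0, 1] multiplies the defect rows.
#' @param noise a [noise_model()].
#' @return list(image, cv, cv_excluding_defects, manifest).
#' @export
synth_emission_image <- function(base_intensity = 100, shape = c(64, 64),
                                 defects = NULL,
                                 noise = noise_model("poisson_counts",
                                                     1, seed = 1)) {
  if (any(shape < 64)) stop("image shape must be >= 64 x 64")
  img <- matrix(base_intensity, shape[1], shape[2])
  defect_rows <- integer(0)
  if (!is.null(defects)) {
    for (i in seq_len(nrow(defects))) {
      r0 <- defects$row[i]; wdef <- defects$width[i]
      rows <- r0:(r0 + wdef - 1)
      if (any(rows < 1 | rows > shape[1]))
        stop("defect at row ", r0, " (width ", wdef,
             ") lies outside the image")
      img[rows, ] <- img[rows, ] * defects$attenuation[i]
      defect_rows <- union(defect_rows, rows)
    }
  }
  img <- matrix(.apply_noise(as.vector(img), noise), shape[1], shape[2])
  cv <- function(x) if (mean(x) > 0) stats::sd(x) / mean(x) else 0
  keep <- setdiff(seq_len(shape[1]), defect_rows)
  list(image = img, cv = cv(as.vector(img)),
       cv_excluding_defects = cv(as.vector(img[keep, , drop = FALSE])),
       manifest = .manifest("synth_emission_image",
                            list(base = base_intensity, shape = shape,
                                 defects = defects), noise))
}

#' Write an emission image as plain-text portable graymap (PGM, P2)
#'
#' @param img numeric matrix (>= 0).
#' @param path output file.
#' @param maxval gray levels (default 65535, 16-bit range).
#' @export
write_pgm <- function(img, path, maxval = 65535) {
  sc <- if (max(img) > 0) maxval / max(img) else 1
  q <- round(pmax(img, 0) * sc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
             con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Synthetic analyte dose series -> dose-response dataset
#'
#' For each mass: maps mass to film thickness, simulates the emission
#' spectrum with that analyte layer (full solver), generates noisy
#' replicate spectra for the covered and bare regions, and records the
#' band-integrated differential response per replicate.
#'
#' @param masses_pg positive ascending masses (pg).
#' @param device bare \code{liet_device} (sensing variant recommended).
#' @param bands a \code{liet_bands}.
#' @param V_b bias (V).
#' @param NA_obj collection NA.
#' @param band response band (nm).
#' @param noise a [noise_model()] (poisson_counts; its scale is the
#'   expected number of counts per spectral sample at the bare-spectrum
#'   peak, default 200, the count-rate scale of EMCCD emission spectra;
#'   per-replicate seeds are derived from its seed).
#' @param replicates >= 2 replicate spectra per dose.
#' @param lambda_nm wavelength grid covering the band.
#' @param N,n_theta,n_dipoles solver settings.
#' @param density_g_cm3,area_um2 mass-to-thickness mapping, see
#'   [mass_to_thickness()].
#' @param analyte_material material name for the film.
#' @return list(responses = data.frame(mass_pg, thickness_nm,
#'   response_mean, response_sd, n_replicates), noise_level (s.d. of the
#'   bare-reference response across replicates), per_replicate, manifest).
#' @export
analyte_dose_series <- function(masses_pg, device, bands, V_b = 2.8,
                                NA_obj = 0.3, band = c(620, 700),
                                noise = noise_model("poisson_counts", 200,
                                                    seed = 1),
                                replicates = 3,
                                lambda_nm = seq(560, 760, by = 2.5),
                                N = 21, n_theta = 9, n_dipoles = 11,
                                density_g_cm3 = 1.42, area_um2 = 2500,
                                analyte_material = "analyte") {
  if (any(masses_pg <= 0) || is.unsorted(masses_pg))
    stop("masses must be positive ascending")
  if (replicates < 2) stop("need >= 2 replicates")
  th_nm <- mass_to_thickness(masses_pg, density_g_cm3, area_um2)
  if (any(th_nm > 100))
    stop("film thickness ", signif(max(th_nm), 3),
         " nm beyond the solver-validated range (0-100 nm)")
  mk_spec <- function(dev) {
    G <- photonic_contribution(dev, lambda_nm, NA_obj = NA_obj,
                               n_theta = n_theta, n_dipoles = n_dipoles,
                               N = N, normalize = FALSE)
    H <- spectral_electronic_contribution(bands, V_b, lambda_nm,
                                          normalize = FALSE)
    data.frame(lambda_nm = lambda_nm, intensity = H$H * G$G)
  }
  bare_model <- mk_spec(device)
  # normalize model intensities to order unity so the Poisson counts scale
  # (counts per unit intensity) is meaningful
  norm <- max(bare_model$intensity)
  bare_model$intensity <- bare_model$intensity / norm
  # the 2.5 nm smoothing convention needs >= 2 grid steps; widen the
  # window on coarse simulation grids
  smooth_nm <- max(2.5, 2 * stats::median(diff(lambda_nm)))
  noisy_response <- function(model_cov, rep_seed) {
    nz <- noise_model(noise$kind, noise$scale, rep_seed)
    nz2 <- noise_model(noise$kind, noise$scale, rep_seed + 1L)
    sa <- synth_spectrum(model_cov, nz, smooth_window_nm = smooth_nm)
    sb <- synth_spectrum(bare_model, nz2, smooth_window_nm = smooth_nm)
    differential_band_signal(
      data.frame(lambda_nm = lambda_nm, intensity = sa$smoothed),
      data.frame(lambda_nm = lambda_nm, intensity = sb$smoothed), band)
  }
  per_rep <- list()
  rows <- list()
  for (i in seq_along(masses_pg)) {
    dev_i <- device
    dev_i$overlayer <- list(material = analyte_material,
                            thickness_nm = th_nm[i])
    model_i <- mk_spec(dev_i)
    model_i$intensity <- model_i$intensity / norm
    rs <- vapply(seq_len(replicates), function(k)
      noisy_response(model_i, noise$seed + 1000L * i + 2L * k),
      numeric(1))
    per_rep[[i]] <- rs
    rows[[i]] <- data.frame(mass_pg = masses_pg[i], thickness_nm = th_nm[i],
                            response_mean = mean(rs),
                            response_sd = stats::sd(rs),
                            n_replicates = replicates)
  }
  # noise level: bare-vs-bare replicate responses
  bare_rs <- vapply(seq_len(replicates + 3), function(k)
    noisy_response(bare_model, noise$seed + 777L + 2L * k), numeric(1))
  out <- list(responses = do.call(rbind, rows),
              noise_level = stats::sd(bare_rs),
              bare_replicates = bare_rs,
              per_replicate = per_rep,
              manifest = .manifest("analyte_dose_series",
                                   list(masses_pg = masses_pg, V_b = V_b,
                                        NA_obj = NA_obj, band = band,
                                        replicates = replicates,
                                        density_g_cm3 = density_g_cm3,
                                        area_um2 = area_um2,
                                        N = N, n_theta = n_theta),
                                   noise))
  out
}
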
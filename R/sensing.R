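## Refractometric sensing readout: band-integrated differential emission,
## peak fold-change, dose-response assembly and the triple-noise limit of
## detection.

.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Band-integrated differential emission signal
#'
#' (integral_band I_analyte - integral_band I_bare) / integral_band I_bare
#' by the trapezoid rule over the grid points inside the band.
#'
#' @param I_analyte,I_bare spectra (data.frames with \code{lambda_nm},
#'   \code{intensity}) on one common grid.
#' @param band c(min, max) nm, inside the grid; default 620-700 nm.
#' @return dimensionless response.
#' @export
differential_band_signal <- function(I_analyte, I_bare,
                                     band = c(620, 700)) {
  lam <- I_bare$lambda_nm
  if (length(lam) != length(I_analyte$lambda_nm) ||
      any(abs(lam - I_analyte$lambda_nm) > 1e-9))
    stop("spectra must share one wavelength grid")
  if (band[1] < min(lam) || band[2] > max(lam))
    stop("band outside the spectral grid")
  sel <- lam >= band[1] & lam <= band[2]
  if (sum(sel) < 2) stop("band contains fewer than 2 grid points")
  ref <- .trapz(lam[sel], I_bare$intensity[sel])
  if (ref <= 0) stop("degenerate reference: bare band integral is zero")
  (.trapz(lam[sel], I_analyte$intensity[sel]) - ref) / ref
}

#' Peak fold-change between analyte-covered and bare spectra
#'
#' Ratio of parabolically interpolated peak heights inside a search window
#' (550-750 nm by default, the short-wavelength antenna peak).
#'
#' @inheritParams differential_band_signal
#' @param window search window, nm.
#' @return ratio analyte/bare of interpolated peak heights. Warns when a
#'   peak sits at a window edge.
#' @export
peak_fold_change <- function(I_analyte, I_bare, window = c(550, 750)) {
  pa <- find_peak(I_analyte$lambda_nm, I_analyte$intensity, window)
  pb <- find_peak(I_bare$lambda_nm, I_bare$intensity, window)
  pa$height / pb$height
}

#' Triple-noise limit of detection from a dose-response table
#'
#' Smallest analyte mass at which the piecewise-linearly interpolated mean
#' response crosses 3x the noise level. Non-monotone means trigger a
#' warning and an isotonic-regression fallback; a crossing below the lowest
#' dose is reported as extrapolated.
#'
#' @param responses data.frame with columns \code{mass_pg},
#'   \code{response_mean} (and optionally \code{response_sd},
#'   \code{n_replicates}).
#' @param noise_level dimensionless noise level sigma (> 0); the LOD
#'   threshold is \code{3 * noise_level}.
#' @return list(lod_pg, threshold, bracket = c(lo, hi) doses surrounding
#'   the crossing, extrapolated, isotonic_used). \code{lod_pg} is NA (with
#'   bracket NULL) when the response never reaches the threshold.
#' @export
limit_of_detection <- function(responses, noise_level) {
  stopifnot(noise_level > 0)
  r <- responses[order(responses$mass_pg), ]
  if (nrow(r) < 3) stop("need >= 3 dose points")
  m <- r$mass_pg; y <- r$response_mean
  iso_used <- FALSE
  if (any(diff(y) < 0)) {
    warning("non-monotone mean responses; applying isotonic regression")
    y <- stats::isoreg(m, y)$yf
    iso_used <- TRUE
  }
  thr <- 3 * noise_level
  if (max(y) < thr)
    return(list(lod_pg = NA_real_, threshold = thr, bracket = NULL,
                extrapolated = FALSE, isotonic_used = iso_used))
  if (y[1] >= thr) {
    # crossing below the lowest dose: extrapolate the first segment
    slope <- (y[2] - y[1]) / (m[2] - m[1])
    lod <- if (slope > 0) m[1] - (y[1] - thr) / slope else m[1]
    return(list(lod_pg = max(lod, 0), threshold = thr,
                bracket = c(0, m[1]), extrapolated = TRUE,
                isotonic_used = iso_used))
  }
  i <- which(y >= thr)[1]
  lod <- m[i - 1] + (thr - y[i - 1]) * (m[i] - m[i - 1]) /
    (y[i] - y[i - 1])
  list(lod_pg = lod, threshold = thr, bracket = c(m[i - 1], m[i]),
       extrapolated = FALSE, isotonic_used = iso_used)
}

#' Analyte mass to film thickness
#'
#' thickness = mass / (density x collection area). The density and area
#' defaults are configuration choices of this package (documented in the
#' methods vignette), not literature-derived.
#'
#' @param mass_pg analyte mass (pg).
#' @param density_g_cm3 film density; default 1.42 (crystalline-amino-acid
#'   scale).
#' @param area_um2 signal-collection area; default 2500 (50 x 50 um).
#' @return film thickness, nm.
#' @export
mass_to_thickness <- function(mass_pg, density_g_cm3 = 1.42,
                              area_um2 = 2500) {
  stopifnot(all(mass_pg >= 0), density_g_cm3 > 0, area_um2 > 0)
  # pg / (g cm^-3 * um^2): 1 pg = 1e-12 g, 1 um^2 = 1e-8 cm^2,
  # result in cm -> nm (1 cm = 1e7 nm)
  (mass_pg * 1e-12) / (density_g_cm3 * area_um2 * 1e-8) * 1e7
}
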
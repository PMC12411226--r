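## Combining the electronic and photonic factors into emission spectra:
## I(w, Vb) = H(w, Vb) * G(w), pointwise on a shared wavelength grid.
## Because the two factors separate, intensity ratios between biases at a
## fixed wavelength depend only on H -- a structural property the test
## suite uses as a regression check.

#' Emission spectrum as the product of H and G
#'
#' @param H a \code{liet_hspectrum} (see
#'   [spectral_electronic_contribution()]).
#' @param G a \code{liet_gspectrum} (see [photonic_contribution()]), or any
#'   data.frame with columns \code{lambda_nm}, \code{G} on the identical
#'   grid. Grids must match exactly; no silent interpolation.
#' @return object of class \code{liet_emission}: data.frame(lambda_nm,
#'   intensity), attributes \code{V_b}, \code{NA_obj}, \code{scale}
#'   (product of the factor scales).
#' @export
liet_spectrum <- function(H, G) {
  if (length(H$lambda_nm) != length(G$lambda_nm) ||
      any(abs(H$lambda_nm - G$lambda_nm) > 1e-9))
    stop("wavelength grids of H and G differ; align them explicitly")
  out <- data.frame(lambda_nm = H$lambda_nm, intensity = H$H * G$G)
  attr(out, "V_b") <- attr(H, "V_b")
  attr(out, "NA_obj") <- attr(G, "NA_obj")
  sH <- attr(H, "scale"); sG <- attr(G, "scale")
  attr(out, "scale") <- (if (is.null(sH)) 1 else sH) *
    (if (is.null(sG)) 1 else sG)
  class(out) <- c("liet_emission", "data.frame")
  out
}

#' Parabolic-interpolated peak of a spectrum
#'
#' Locates the grid maximum inside a search window and refines position and
#' height with a parabola through the three surrounding samples, making the
#' peak estimate effectively grid-independent.
#'
#' @param lambda_nm,y spectrum samples.
#' @param window c(min, max) search window in nm.
#' @return list(lambda, height, at_edge); \code{at_edge} is TRUE (with a
#'   warning) when the window maximum sits on the window boundary, i.e.
#'   there is no interior peak.
#' @export
find_peak <- function(lambda_nm, y, window = c(550, 750)) {
  sel <- which(lambda_nm >= window[1] & lambda_nm <= window[2])
  if (length(sel) < 3) stop("window contains fewer than 3 samples")
  i <- sel[which.max(y[sel])]
  if (i == sel[1] || i == sel[length(sel)]) {
    warning("peak lies at the search-window edge (", lambda_nm[i], " nm)")
    return(list(lambda = lambda_nm[i], height = y[i], at_edge = TRUE))
  }
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- y0 - 2 * y1 + y2
  dx <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y0 - y2) / denom
  h <- lambda_nm[i + 1] - lambda_nm[i]
  list(lambda = lambda_nm[i] + dx * h,
       height = y1 - 0.25 * (y0 - y2) * dx,
       at_edge = FALSE)
}

#' Highest interior local maximum of a spectrum
#'
#' Unlike [find_peak()], which takes the window maximum, this scans for
#' interior local maxima (samples exceeding both neighbours), picks the
#' highest, and refines it parabolically; boundary samples never qualify.
#'
#' @param lambda_nm,y spectrum samples.
#' @return list(lambda, height) or NULL when no interior maximum exists.
#' @export
interior_peak <- function(lambda_nm, y) {
  n <- length(y)
  if (n < 3) return(NULL)
  i_all <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n]) + 1
  if (length(i_all) == 0) return(NULL)
  i <- i_all[which.max(y[i_all])]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  den <- y0 - 2 * y1 + y2
  dx <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / den
  h <- lambda_nm[i + 1] - lambda_nm[i]
  list(lambda = lambda_nm[i] + dx * h,
       height = y1 - 0.25 * (y0 - y2) * dx)
}

#' Emission spectra across a bias family
#'
#' Computes G once (it is bias-independent), H per bias with a shared
#' normalization, and returns the product family plus per-bias peak
#' wavelengths.
#'
#' @param device a \code{liet_device}.
#' @param bands a \code{liet_bands}.
#' @param biases ascending positive biases (V).
#' @param lambda_nm wavelength grid.
#' @param NA_obj collection NA.
#' @param N,n_theta,n_dipoles solver settings.
#' @param G optional precomputed \code{liet_gspectrum} on the same grid.
#' @param peak_window window for the short-wavelength peak report.
#' @return list(spectra = named list of \code{liet_emission}, G =, H =,
#'   peaks = data.frame(V_b, lambda_peak, height)).
#' @export
spectra_vs_bias <- function(device, bands, biases, lambda_nm,
                            NA_obj = 0.8, N = 41, n_theta = 13,
                            n_dipoles = 15, G = NULL,
                            peak_window = c(550, 750)) {
  if (is.unsorted(biases)) stop("biases must be sorted ascending")
  if (is.null(G))
    G <- photonic_contribution(device, lambda_nm, NA_obj = NA_obj,
                               n_theta = n_theta, n_dipoles = n_dipoles,
                               N = N)
  Hs <- h_vs_bias(bands, biases, lambda_nm)
  spectra <- lapply(Hs, liet_spectrum, G = G)
  peaks <- do.call(rbind, lapply(seq_along(biases), function(i) {
    sp <- spectra[[i]]
    pk <- tryCatch(find_peak(sp$lambda_nm, sp$intensity, peak_window),
                   warning = function(w)
                     suppressWarnings(find_peak(sp$lambda_nm, sp$intensity,
                                                peak_window)))
    data.frame(V_b = biases[i], lambda_peak = pk$lambda,
               height = pk$height, at_edge = pk$at_edge)
  }))
  list(spectra = spectra, G = G, H = Hs, peaks = peaks)
}

#' Angle-resolved emission map H x curly_G in (k0, k_par) space
#'
#' @param device,bands device and electronic model.
#' @param V_b bias (V).
#' @param lambda_nm wavelength grid (>= 100 points recommended).
#' @param theta_rad polar angles in glass (>= 30 points recommended).
#' @param N,n_dipoles solver settings.
#' @param map optional precomputed [photonic_map()].
#' @return list: \code{lambda_nm}, \code{theta_rad}, matrix \code{I}
#'   (lambda x theta), \code{k_par_um} (in-glass in-plane wavevector,
#'   um^-1), \code{k0_um}, and the underlying \code{map} and \code{H}.
#' @export
angle_resolved_emission <- function(device, bands, V_b, lambda_nm,
                                    theta_rad, N = 41, n_dipoles = 15,
                                    map = NULL) {
  if (is.null(map))
    map <- photonic_map(device, lambda_nm, theta_rad, n_dipoles = n_dipoles,
                        N = N)
  H <- spectral_electronic_contribution(bands, V_b, map$lambda_nm)
  I <- map$G * H$H
  list(lambda_nm = map$lambda_nm, theta_rad = map$theta_rad, I = I,
       k_par_um = map$k_par_um,
       k0_um = 2 * pi / (map$lambda_nm / 1000), map = map, H = H)
}

#' Wavelength of the angle-independent (dispersionless) map feature
#'
#' For each collection angle, locates the interior peak of the map inside a
#' long-wavelength window; the dispersionless feature is identified by the
#' peak set whose wavelength varies least across angles (reported with its
#' spread).
#'
#' @param map a [photonic_map()] or the \code{I}-carrying result of
#'   [angle_resolved_emission()].
#' @param window wavelength window to search (nm).
#' @return list(lambda = median peak wavelength, spread = max - min across
#'   angles, per_angle = vector).
#' @export
dispersionless_feature <- function(map, window = c(850, 1200)) {
  M <- if (!is.null(map$I)) map$I else map$G
  lam <- map$lambda_nm
  pk <- vapply(seq_along(map$theta_rad), function(j) {
    suppressWarnings(find_peak(lam, M[, j], window)$lambda)
  }, numeric(1))
  list(lambda = stats::median(pk), spread = max(pk) - min(pk),
       per_angle = pk)
}
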
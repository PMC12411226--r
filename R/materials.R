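## Material optical models.
##
## Metals are bundled as coarse tabulated n,k data from the standard
## literature compilations used throughout plasmonics (Johnson & Christy
## style tables for Au and Cr, evaporated-film compilation for Al),
## interpolated log-linearly in wavelength. Dielectrics default to constant
## refractive indices. With the exp(-i w t) convention, passivity requires
## Im(eps) >= 0, which holds for n, k >= 0 since eps = (n + i k)^2.

# Tabulated n, k vs wavelength (nm), 380-1250 nm.  Coarse sampling is
# deliberate: the package's own documentation flags that absolute resonance
# positions can shift by a few tens of nm with the choice of dataset.
.liet_nk_tables <- list(
  Au = data.frame(
    lambda_nm = c(397, 413, 430, 451, 471, 496, 521, 549, 582, 617, 660,
                  705, 756, 821, 892, 984, 1088, 1216, 1393),
    n = c(1.470, 1.460, 1.450, 1.380, 1.310, 1.040, 0.616, 0.430, 0.290,
          0.209, 0.141, 0.131, 0.140, 0.160, 0.177, 0.225, 0.273, 0.350,
          0.430),
    k = c(1.952, 1.958, 1.948, 1.920, 1.810, 1.833, 2.090, 2.455, 2.860,
          3.280, 3.690, 4.100, 4.542, 5.080, 5.660, 6.430, 7.155, 8.145,
          9.500)
  ),
  Al = data.frame(
    lambda_nm = c(380, 400, 450, 500, 550, 600, 650, 700, 750, 800, 826,
                  850, 900, 950, 1000, 1100, 1200, 1250, 1400),
    n = c(0.454, 0.490, 0.618, 0.769, 0.958, 1.200, 1.470, 1.830, 2.400,
          2.800, 2.750, 2.610, 2.060, 1.670, 1.350, 1.260, 1.210, 1.260,
          1.380),
    k = c(4.610, 4.860, 5.470, 6.080, 6.690, 7.260, 7.790, 8.310, 8.620,
          8.450, 8.310, 8.220, 8.300, 8.800, 9.580, 10.700, 11.900, 12.500,
          13.600)
  ),
  Cr = data.frame(
    lambda_nm = c(380, 400, 450, 500, 550, 600, 650, 700, 750, 800, 850,
                  900, 1000, 1100, 1250, 1400),
    n = c(2.020, 2.080, 2.340, 2.490, 2.750, 3.030, 3.250, 3.400, 3.520,
          3.620, 3.730, 3.840, 4.080, 4.270, 4.400, 4.500),
    k = c(2.590, 2.660, 3.050, 3.430, 3.790, 4.080, 4.290, 4.350, 4.350,
          4.340, 4.340, 4.370, 4.470, 4.660, 5.000, 5.300)
  )
)

#' Construct a material optical model
#'
#' A material is one of three permittivity models: \code{tabulated} n,k data
#' interpolated log-linearly in wavelength, a \code{constant_index}
#' (dispersionless) dielectric, or a \code{drude_lorentz} analytic model.
#'
#' @param name identifier, e.g. "Au".
#' @param kind one of \code{"tabulated"}, \code{"constant_index"},
#'   \code{"drude_lorentz"}.
#' @param table for \code{tabulated}: data.frame with columns
#'   \code{lambda_nm}, \code{n}, \code{k}; \code{lambda_nm} strictly
#'   increasing, \code{k >= 0}.
#' @param n for \code{constant_index}: the (real, >= 1e-6) refractive index.
#' @param eps_inf,wp_ev,gamma_ev,oscillators for \code{drude_lorentz}:
#'   background permittivity, plasma frequency and damping (eV), plus an
#'   optional data.frame of Lorentz oscillators with columns \code{f},
#'   \code{w0_ev}, \code{gamma_ev}.
#' @return object of class \code{liet_material}.
#' @seealso [permittivity()], [liet_material_db()]
#' @export
material_model <- function(name, kind = c("tabulated", "constant_index",
                                          "drude_lorentz"),
                           table = NULL, n = NULL,
                           eps_inf = 1, wp_ev = NULL, gamma_ev = NULL,
                           oscillators = NULL) {
  kind <- match.arg(kind)
  m <- list(name = name, kind = kind)
  if (kind == "tabulated") {
    stopifnot(is.data.frame(table),
              all(c("lambda_nm", "n", "k") %in% names(table)))
    if (any(diff(table$lambda_nm) <= 0))
      stop("tabulated data for '", name, "' must be strictly increasing in lambda")
    if (any(table$k < 0))
      stop("tabulated data for '", name, "' has k < 0 (non-passive)")
    m$table <- table[, c("lambda_nm", "n", "k")]
  } else if (kind == "constant_index") {
    stopifnot(is.numeric(n), length(n) == 1, n >= 1e-6)
    m$n <- n
  } else {
    stopifnot(is.numeric(wp_ev), is.numeric(gamma_ev), gamma_ev >= 0)
    m$eps_inf <- eps_inf; m$wp_ev <- wp_ev; m$gamma_ev <- gamma_ev
    m$oscillators <- oscillators
  }
  class(m) <- "liet_material"
  m
}

#' @export
print.liet_material <- function(x, ...) {
  cat("<liet_material>", x$name, "(", x$kind, ")\n")
  if (x$kind == "tabulated")
    cat("  range:", min(x$table$lambda_nm), "-", max(x$table$lambda_nm), "nm\n")
  if (x$kind == "constant_index") cat("  n =", x$n, "\n")
  invisible(x)
}

#' Bundled material database
#'
#' Returns the bundled materials: tabulated Au, Cr, Al; constant-index
#' alumina (1.76), glass (1.52), PMMA (1.49), a generic analyte (default
#' n = 1.50, overridable), vacuum and air.
#'
#' @param analyte_n refractive index assigned to the "analyte" entry.
#' @return named list of \code{liet_material}.
#' @export
liet_material_db <- function(analyte_n = 1.50) {
  list(
    Au      = material_model("Au", "tabulated", table = .liet_nk_tables$Au),
    Cr      = material_model("Cr", "tabulated", table = .liet_nk_tables$Cr),
    Al      = material_model("Al", "tabulated", table = .liet_nk_tables$Al),
    Al2O3   = material_model("Al2O3", "constant_index", n = 1.76),
    glass   = material_model("glass", "constant_index", n = 1.52),
    PMMA    = material_model("PMMA", "constant_index", n = 1.49),
    analyte = material_model("analyte", "constant_index", n = analyte_n),
    vacuum  = material_model("vacuum", "constant_index", n = 1.0),
    air     = material_model("air", "constant_index", n = 1.0)
  )
}

#' Complex relative permittivity of a material
#'
#' For tabulated materials n and k are interpolated linearly in log(lambda)
#' (the bundled tables only support interpolation, not extrapolation); the
#' permittivity is (n + i k)^2. Constant-index materials return n^2.
#'
#' @param material a \code{liet_material}.
#' @param lambda_nm vacuum wavelength(s), nm; must lie inside a tabulated
#'   material's table range.
#' @return complex permittivity, same length as \code{lambda_nm}.
#' @export
#' @examples
#' db <- liet_material_db()
#' permittivity(db$glass, 650)        # 2.3104+0i
#' Re(permittivity(db$Au, 650)) < 0   # metallic
permittivity <- function(material, lambda_nm) {
  stopifnot(inherits(material, "liet_material"), all(lambda_nm > 0))
  switch(material$kind,
    constant_index = rep(complex(real = material$n^2, imaginary = 0),
                         length(lambda_nm)),
    tabulated = {
      tb <- material$table
      lo <- min(tb$lambda_nm); hi <- max(tb$lambda_nm)
      if (any(lambda_nm < lo | lambda_nm > hi))
        stop("wavelength out of range for material '", material$name,
             "': table covers [", lo, ", ", hi, "] nm")
      lx <- log(tb$lambda_nm)
      n <- stats::approx(lx, tb$n, xout = log(lambda_nm))$y
      k <- stats::approx(lx, tb$k, xout = log(lambda_nm))$y
      (complex(real = n, imaginary = k))^2
    },
    drude_lorentz = {
      w <- ev_from_nm(lambda_nm)
      eps <- material$eps_inf -
        material$wp_ev^2 / (w^2 + 1i * material$gamma_ev * w)
      if (!is.null(material$oscillators)) {
        for (i in seq_len(nrow(material$oscillators))) {
          o <- material$oscillators[i, ]
          eps <- eps + o$f * material$wp_ev^2 /
            (o$w0_ev^2 - w^2 - 1i * o$gamma_ev * w)
        }
      }
      eps
    }
  )
}
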
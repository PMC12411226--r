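## Spectral electronic contribution H(w, Vb) of inelastic tunnelling.
##
## Electrons tunnel from the Al bottom electrode into the Cr layer (the Au
## above the thin Cr is neglected in the electronic factor). An electron of
## initial energy Ei (measured from Al's own chemical potential) reaches a
## final state Ef (measured from Cr's chemical potential) while emitting a
## photon hbar*w; the energy-conservation delta fixes Ef = Ei + e Vb -
## hbar*w, leaving a single integral
##   H(w, Vb) = int dE rho_Al(E) f_Al(E) rho_Cr(E') [1 - f_Cr(E')],
##   E' = E + e Vb - hbar w.
## At T -> 0 this forces hbar w <= e Vb (quantum cut-off); at 300 K the edge
## is thermally smeared over a few kB T.

#' Fermi-Dirac occupation
#'
#' Numerically stable for |E - mu| / kB T up to +-500 and beyond (uses
#' \code{plogis}).
#'
#' @param E energy, eV (vectorized).
#' @param mu chemical potential, eV.
#' @param T_K temperature, K (> 0).
#' @return occupation fraction in [0, 1].
#' @export
#' @examples
#' fermi_occupation(0, 0, 300)  # 0.5
fermi_occupation <- function(E, mu = 0, T_K = 300) {
  if (T_K <= 0) stop("T must be > 0")
  stats::plogis((mu - E) / (liet_constants$kB_ev * T_K))
}

#' Electronic-band model for the two tunnelling electrodes
#'
#' Each metal carries a density-of-states model on an energy axis whose zero
#' is that metal's own chemical potential; the default is a free-electron
#' rho(E) proportional to sqrt(E - E_bottom) with the band bottom E_bottom
#' eV below the chemical potential (Al 11.7 eV, Cr 7.0 eV). A tabulated
#' rho(E) (data.frame with columns E_ev, rho) can be substituted per metal.
#'
#' @param emitter_depth_ev band-bottom depth of the emitter (Al), eV.
#' @param receptor_depth_ev band-bottom depth of the receptor (Cr), eV.
#' @param T_K electron temperature, K.
#' @param emitter_dos,receptor_dos optional tabulated DOS tables.
#' @return object of class \code{liet_bands}.
#' @export
electronic_bands <- function(emitter_depth_ev = 11.7,
                             receptor_depth_ev = 7.0, T_K = 300,
                             emitter_dos = NULL, receptor_dos = NULL) {
  stopifnot(emitter_depth_ev > 0, receptor_depth_ev > 0, T_K > 0)
  b <- list(emitter_depth_ev = emitter_depth_ev,
            receptor_depth_ev = receptor_depth_ev, T_K = T_K,
            emitter_dos = emitter_dos, receptor_dos = receptor_dos)
  class(b) <- "liet_bands"
  b
}

.dos_eval <- function(E, depth_ev, table = NULL) {
  if (is.null(table)) {
    r <- sqrt(pmax(E + depth_ev, 0))
  } else {
    r <- stats::approx(table$E_ev, table$rho, xout = E, yleft = 0,
                       yright = table$rho[nrow(table)])$y
    r[r < 0] <- 0
  }
  r
}

#' Spectral electronic contribution H(w, Vb)
#'
#' Evaluates the single-integral form of the tunnelling spectral weight on a
#' wavelength grid at a fixed positive bias. The integral is a trapezoid sum
#' on an energy grid no coarser than kB T / 2 (a coarser user-supplied
#' \code{dE_ev} triggers a resolution warning).
#'
#' @param bands a \code{liet_bands}.
#' @param V_b bias, volts (> 0).
#' @param lambda_nm wavelength grid, nm.
#' @param dE_ev energy-grid step, eV; defaults to min(kB T / 2, 5 meV).
#' @param normalize if TRUE (default) scale so max(H) = 1 and store the
#'   scale in attribute \code{scale} so that ratios across biases stay
#'   meaningful (H_physical = H * scale).
#' @return object of class \code{liet_hspectrum}: data.frame with columns
#'   \code{lambda_nm}, \code{H}; attributes \code{V_b}, \code{scale},
#'   \code{T_K}.
#' @export
spectral_electronic_contribution <- function(bands, V_b, lambda_nm,
                                             dE_ev = NULL,
                                             normalize = TRUE) {
  stopifnot(inherits(bands, "liet_bands"))
  if (V_b <= 0) stop("V_b must be > 0")
  stopifnot(all(lambda_nm > 0))
  kT <- liet_constants$kB_ev * bands$T_K
  if (is.null(dE_ev)) dE_ev <- min(kT / 2, 0.005)
  if (dE_ev > kT / 2)
    warning("energy grid (", signif(dE_ev, 3),
            " eV) is coarser than kB*T/2 = ", signif(kT / 2, 3),
            " eV; thermal tails may be unresolved")
  hw <- ev_from_nm(lambda_nm)
  # Integration support: emitter occupied states down to the band bottom,
  # up to a thermal tail above mu.
  Emin <- -bands$emitter_depth_ev
  Emax <- 30 * kT
  Egrid <- seq(Emin, Emax, by = dE_ev)
  fAl <- fermi_occupation(Egrid, 0, bands$T_K)
  rhoAl <- .dos_eval(Egrid, bands$emitter_depth_ev, bands$emitter_dos)
  base <- rhoAl * fAl
  H <- vapply(hw, function(w) {
    Ef <- Egrid + V_b - w
    g <- .dos_eval(Ef, bands$receptor_depth_ev, bands$receptor_dos) *
      (1 - fermi_occupation(Ef, 0, bands$T_K))
    y <- base * g
    # trapezoid
    dE_ev * (sum(y) - 0.5 * (y[1] + y[length(y)]))
  }, numeric(1))
  sc <- if (normalize && max(H) > 0) max(H) else 1
  out <- data.frame(lambda_nm = lambda_nm, H = H / sc)
  attr(out, "V_b") <- V_b
  attr(out, "scale") <- sc
  attr(out, "T_K") <- bands$T_K
  class(out) <- c("liet_hspectrum", "data.frame")
  out
}

#' Family of H spectra across biases with shared normalization
#'
#' @param bands a \code{liet_bands}.
#' @param V_b_list positive, ascending biases (V).
#' @param lambda_nm wavelength grid.
#' @param dE_ev optional energy step, see
#'   [spectral_electronic_contribution()].
#' @return named list of \code{liet_hspectrum} (names "V<bias>"), all scaled
#'   by one common factor (the family maximum); each element keeps the
#'   shared scale in its \code{scale} attribute.
#' @export
h_vs_bias <- function(bands, V_b_list, lambda_nm, dE_ev = NULL) {
  if (length(V_b_list) == 0) stop("empty bias list")
  if (any(V_b_list <= 0)) stop("biases must be positive")
  if (is.unsorted(V_b_list)) stop("biases must be sorted ascending")
  raw <- lapply(V_b_list, function(vb)
    spectral_electronic_contribution(bands, vb, lambda_nm, dE_ev = dE_ev,
                                     normalize = FALSE))
  fam_max <- max(vapply(raw, function(h) max(h$H), numeric(1)))
  if (fam_max <= 0) fam_max <- 1
  out <- lapply(raw, function(h) {
    h$H <- h$H / fam_max
    attr(h, "scale") <- fam_max
    h
  })
  names(out) <- paste0("V", format(V_b_list, trim = TRUE))
  out
}

#' Brute-force oracle for H via an explicit 2D integral
#'
#' Independent reference: evaluates the double integral over initial and
#' final energies with the energy-conservation delta replaced by a narrow
#' Gaussian (width sigma_ev), on a dense 2D trapezoid grid. Used by the test
#' suite; far slower than [spectral_electronic_contribution()].
#'
#' @param bands a \code{liet_bands}.
#' @param V_b bias (V).
#' @param hw_ev single photon energy, eV.
#' @param sigma_ev Gaussian delta width, eV.
#' @param dE_ev 2D grid step, eV.
#' @return unnormalized H value.
#' @export
h_bruteforce_2d <- function(bands, V_b, hw_ev, sigma_ev = 0.004,
                            dE_ev = 0.004) {
  kT <- liet_constants$kB_ev * bands$T_K
  Ei <- seq(-bands$emitter_depth_ev, 30 * kT, by = dE_ev)
  Ef <- seq(-bands$receptor_depth_ev, 30 * kT + V_b, by = dE_ev)
  wAl <- .dos_eval(Ei, bands$emitter_depth_ev, bands$emitter_dos) *
    fermi_occupation(Ei, 0, bands$T_K)
  wCr <- .dos_eval(Ef, bands$receptor_depth_ev, bands$receptor_dos) *
    (1 - fermi_occupation(Ef, 0, bands$T_K))
  # delta(Ei - (Ef + hw) + eVb) ~ Gaussian in (Ei - Ef + Vb - hw)
  d <- outer(Ei, Ef, function(a, b) {
    x <- a - b + V_b - hw_ev
    exp(-x^2 / (2 * sigma_ev^2)) / (sqrt(2 * pi) * sigma_ev)
  })
  dE_ev^2 * as.numeric(wAl %*% d %*% wCr)
}
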
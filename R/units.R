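## Physical constants and unit conversions.
## Conventions used throughout the package:
##   lengths in nm, photon/electron energies in eV, bias in volts,
##   temperatures in K, current densities in A m^-2.
## Fields use the exp(-i w t) convention, so passive media have Im(eps) >= 0.

#' Physical constants used by lietsim
#'
#' A named list of the physical constants the package relies on, in the
#' package's working units (nm, eV, V, K, A m^-2).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{hc_ev_nm}{Planck constant times speed of light, eV nm (1239.8420).}
#'   \item{kB_ev}{Boltzmann constant, eV K^-1.}
#'   \item{e_C}{Elementary charge, C.}
#'   \item{h_Js}{Planck constant, J s.}
#'   \item{me_kg}{Electron rest mass, kg.}
#'   \item{hbar_evs}{Reduced Planck constant, eV s.}
#'   \item{k_free_nm}{sqrt(2 me * 1 eV)/hbar in nm^-1 (5.12317): free-electron
#'     wavevector at 1 eV.}
#' }
#' @export
liet_constants <- list(
  hc_ev_nm  = 1239.84198,
  kB_ev     = 8.617333262e-5,
  e_C       = 1.602176634e-19,
  h_Js      = 6.62607015e-34,
  me_kg     = 9.1093837015e-31,
  hbar_evs  = 6.582119569e-16,
  k_free_nm = 5.123167
)

#' Convert vacuum wavelength to photon energy
#'
#' @param lambda_nm wavelength in nm.
#' @return photon energy in eV.
#' @export
#' @examples
#' ev_from_nm(650)    # ~1.907 eV
ev_from_nm <- function(lambda_nm) liet_constants$hc_ev_nm / lambda_nm

#' Convert photon energy to vacuum wavelength
#'
#' @param e_ev photon energy in eV.
#' @return wavelength in nm.
#' @export
nm_from_ev <- function(e_ev) liet_constants$hc_ev_nm / e_ev
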
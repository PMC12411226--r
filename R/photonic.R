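## Antenna-mediated photonic contribution.
##
## The transition dipoles generated by inelastic tunnelling sit inside the
## Al2O3 gap under the wire and point along z (surface normal), so they
## radiate p-polarized light. By optical reciprocity, the far-field
## amplitude g(r_hat, r_l, w) emitted towards r_hat equals (up to one global
## constant, fixed here to 1) the z-component of the field induced at r_l
## by a unit-E-amplitude p-polarized plane wave incident from -r_hat,
## computed with the periodic solver. Dipoles at different x are mutually
## incoherent; the coherent y-sum collapses to a single term under
## y-invariance:
##   curly_G(w, theta) = sum_l |g(theta, x_l)|^2,
##   G(w) = int_0^theta_max dtheta sin(theta) curly_G(w, theta),
## with theta_max = asin(NA). The default collection side is the
## superstrate: the plane-wave incidence angles that reproduce the
## device's near-field anchors (lattice anomaly at 650 nm for theta = 36
## deg) are superstrate-side angles, and asin(NA = 0.8) = 53 deg matches
## the angular extent of the angle-resolved maps.

#' Far-field amplitudes of gap dipoles via reciprocity
#'
#' @param device a \code{liet_device}.
#' @param lambda_nm wavelength (nm).
#' @param theta_rad polar emission angle in the glass substrate.
#' @param x_nm dipole x positions (wire centred at 0); default
#'   [dipole_positions()].
#' @param z_frac depth in the barrier (0 = Al side, 1 = wire side).
#' @param N Fourier harmonics.
#' @param from collection side ("superstrate" default).
#' @param pol must be "p"; an s-polarized request is rejected because the
#'   surface-normal dipoles emit p-polarized light only.
#' @return complex vector of far-field amplitudes g, one per dipole.
#' @export
farfield_amplitude <- function(device, lambda_nm, theta_rad,
                               x_nm = dipole_positions(device),
                               z_frac = 0.5, N = 41,
                               from = "superstrate", pol = "p") {
  if (pol != "p")
    stop("s-polarized far-field amplitudes are identically zero for ",
         "surface-normal gap dipoles; request rejected")
  stack <- rcwa_stack(device, lambda_nm, from = from)
  sol <- rcwa_solve(stack, lambda_nm, theta_rad, N = N)
  rcwa_gap_field(sol, x_nm, z_frac = z_frac)
}

#' Default dipole x positions under the wire
#'
#' @param device a \code{liet_device}.
#' @param n number of positions across the wire footprint (default 15).
#' @return numeric vector of x positions (nm), strictly inside the wire.
#' @export
dipole_positions <- function(device, n = 15) {
  w <- device$wire_width
  seq(-w / 2, w / 2, length.out = n + 2)[seq(2, n + 1)]
}

#' Angle-resolved photonic contribution at one (wavelength, angle)
#'
#' Incoherent sum over dipole x positions (each its own l-group; the
#' coherent y-sum is a single term under y-invariance).
#'
#' @inheritParams farfield_amplitude
#' @return scalar curly-G value (>= 0).
#' @export
angle_resolved_photonic <- function(device, lambda_nm, theta_rad,
                                    x_nm = dipole_positions(device),
                                    z_frac = 0.5, N = 41,
                                    from = "superstrate") {
  if (length(x_nm) == 0) stop("dipole grid must be non-empty")
  g <- farfield_amplitude(device, lambda_nm, theta_rad, x_nm,
                          z_frac = z_frac, N = N, from = from)
  sum(Mod(g)^2)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch)
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1) return(list(x = (a + b) / 2, w = b - a))
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (b - a) / 2 * x[ord] + (a + b) / 2, w = (b - a) / 2 * w[ord])
}

#' NA-integrated photonic contribution G(w)
#'
#' Gauss-Legendre quadrature of sin(theta) * curly_G over the collection
#' cone theta in [0, asin(NA)], with theta the solver's polar angle in the
#' glass half-space (this keeps the leakage branch of the lattice mode
#' inside the NA = 0.8 cone). Angular node spacing coarser than 2 degrees
#' triggers a quadrature warning.
#'
#' @param device a \code{liet_device}.
#' @param lambda_nm wavelength grid (nm).
#' @param NA_obj collection numerical aperture, (0, 1].
#' @param n_theta number of quadrature nodes.
#' @param n_dipoles dipole positions across the wire.
#' @param N Fourier harmonics.
#' @param z_frac dipole depth in the barrier.
#' @param normalize scale so max = 1, storing the scale as attribute
#'   \code{scale}.
#' @param from collection side, "superstrate" (default) or "substrate".
#' @return data.frame(lambda_nm, G) of class \code{liet_gspectrum} with
#'   attributes \code{NA_obj}, \code{scale}.
#' @export
photonic_contribution <- function(device, lambda_nm, NA_obj = 0.8,
                                  n_theta = 13, n_dipoles = 15, N = 41,
                                  z_frac = 0.5, normalize = TRUE,
                                  from = "superstrate") {
  if (!(NA_obj > 0 && NA_obj <= 1)) stop("NA must be in (0, 1]")
  th_max <- asin(NA_obj)
  if (th_max / n_theta > 2 * pi / 180)
    warning("angular quadrature coarser than 2 degrees (",
            signif(th_max / n_theta * 180 / pi, 3), " deg per node)")
  gl <- gauss_legendre(n_theta, 0, th_max)
  xs <- dipole_positions(device, n_dipoles)
  G <- vapply(lambda_nm, function(lam) {
    stack <- rcwa_stack(device, lam, from = from)
    gg <- vapply(gl$x, function(th) {
      sol <- rcwa_solve(stack, lam, th, N = N)
      sum(Mod(rcwa_gap_field(sol, xs, z_frac = z_frac))^2)
    }, numeric(1))
    sum(gl$w * sin(gl$x) * gg)
  }, numeric(1))
  sc <- if (normalize && max(G) > 0) max(G) else 1
  out <- data.frame(lambda_nm = lambda_nm, G = G / sc)
  attr(out, "NA_obj") <- NA_obj
  attr(out, "scale") <- sc
  class(out) <- c("liet_gspectrum", "data.frame")
  out
}

#' Planar-reference photonic contribution (grating removed)
#'
#' Same quadrature as [photonic_contribution()] but with uniform films and
#' the planar reciprocity route; used to quantify the antenna enhancement.
#'
#' @inheritParams photonic_contribution
#' @return data.frame(lambda_nm, G) with attribute \code{scale}.
#' @export
photonic_contribution_planar <- function(device, lambda_nm, NA_obj = 0.8,
                                         n_theta = 13, z_frac = 0.5,
                                         normalize = FALSE,
                                         from = "superstrate") {
  th_max <- asin(NA_obj)
  gl <- gauss_legendre(n_theta, 0, th_max)
  G <- vapply(lambda_nm, function(lam) {
    g <- dipole_farfield_reciprocal(device, lam, gl$x, z_frac = z_frac,
                                    from = from)
    sum(gl$w * sin(gl$x) * Mod(g)^2)
  }, numeric(1))
  sc <- if (normalize && max(G) > 0) max(G) else 1
  out <- data.frame(lambda_nm = lambda_nm, G = G / sc)
  attr(out, "scale") <- sc
  out
}

#' Angle-resolved photonic map curly_G(lambda, theta)
#'
#' @param device a \code{liet_device}.
#' @param lambda_nm wavelength grid.
#' @param theta_rad polar-angle grid in the collection half-space.
#' @param n_dipoles,N,z_frac see [photonic_contribution()].
#' @param from collection side.
#' @return object of class \code{liet_angular_map}: list with
#'   \code{lambda_nm}, \code{theta_rad}, matrix \code{G} (lambda x theta),
#'   and \code{k_par_um} = (2 pi / lambda) n sin(theta) in um^-1 with n
#'   the collection-side index.
#' @export
photonic_map <- function(device, lambda_nm, theta_rad, n_dipoles = 15,
                         N = 41, z_frac = 0.5, from = "superstrate") {
  xs <- dipole_positions(device, n_dipoles)
  G <- matrix(NA_real_, length(lambda_nm), length(theta_rad))
  for (i in seq_along(lambda_nm)) {
    stack <- rcwa_stack(device, lambda_nm[i], from = from)
    for (j in seq_along(theta_rad)) {
      sol <- rcwa_solve(stack, lambda_nm[i], theta_rad[j], N = N)
      G[i, j] <- sum(Mod(rcwa_gap_field(sol, xs, z_frac = z_frac))^2)
    }
  }
  n_col <- if (from == "superstrate") 1 else 1.52
  kpar <- outer(2 * pi / (lambda_nm / 1000), n_col * sin(theta_rad))
  out <- list(lambda_nm = lambda_nm, theta_rad = theta_rad, G = G,
              k_par_um = kpar, n_collect = n_col, from = from)
  class(out) <- "liet_angular_map"
  out
}

#' Rayleigh-anomaly (grating-equation) wavelengths
#'
#' Wavelengths at which diffraction order m grazes in a medium of index
#' n_medium, for incidence in-plane wavevector kx/k0 = n_in sin(theta):
#' lambda = (P / m) (s n_medium - n_in sin(theta)), s = +-1.
#'
#' @param P period (nm).
#' @param n_sin n_in * sin(theta) (vectorized).
#' @param m diffraction order (non-zero integer).
#' @param n_medium index of the medium in which the order grazes.
#' @return matrix with columns for s = +1 and s = -1 (negative/NA entries
#'   mean no physical anomaly).
#' @export
grating_anomaly_lambda <- function(P, n_sin, m = 1, n_medium = 1.52) {
  lp <- (P / m) * (n_medium - n_sin)
  lm <- (P / m) * (-n_medium - n_sin)
  cbind(plus = ifelse(lp > 0, lp, NA_real_),
        minus = ifelse(-lm > 0, -lm, NA_real_))
}

#' RCWA convergence check in the number of harmonics
#'
#' @param stack an [rcwa_stack()].
#' @param lambda_nm,theta_rad evaluation point.
#' @param N harmonics; compared against N + 20.
#' @param quantity "R" (total reflectance) or "gap" (gap-field intensity
#'   summed over default positions).
#' @param tol relative-change threshold for the convergence warning.
#' @return list(value_N, value_N20, rel_change); warns if rel_change > tol.
#' @export
rcwa_convergence <- function(stack, lambda_nm, theta_rad, N = 41,
                             quantity = c("R", "gap"), tol = 0.01) {
  quantity <- match.arg(quantity)
  val <- function(n) {
    sol <- rcwa_solve(stack, lambda_nm, theta_rad, N = n)
    if (quantity == "R") sol$Rtot
    else sum(Mod(rcwa_gap_field(sol, seq(-40, 40, by = 10)))^2)
  }
  v1 <- val(N); v2 <- val(N + 20)
  rel <- abs(v2 - v1) / max(abs(v2), .Machine$double.eps)
  if (rel > tol)
    warning("RCWA not converged at N = ", N, ": value ", signif(v1, 6),
            " vs ", signif(v2, 6), " at N = ", N + 20,
            " (rel. change ", signif(rel, 3), ")")
  list(value_N = v1, value_N20 = v2, rel_change = rel)
}
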
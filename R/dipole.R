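## Buried-dipole far fields in a planar multilayer: the two independent
## routes used to validate the reciprocity shortcut.
##
## Route 1 (direct): classic source-in-cavity construction. A vertical
## (z-oriented) dipole line in the gap layer radiates TM angular-spectrum
## components with source amplitude s(kx) = kx / kz_s towards both
## half-stacks; multiple reflections between the half-stacks (coefficients
## from TMM sub-problems) build the wave transmitted into the collection
## half-space. The far-field amplitude along the collection polar angle
## theta carries the stationary-phase weight cos(theta).
##
## Route 2 (reciprocity): the same amplitude, up to a theta-independent
## constant, is the z-component of the electric field induced at the dipole
## position by a unit-E-amplitude p-polarized plane wave sent from the
## observation direction.

#' Direct dipole-in-multilayer far-field amplitude (planar oracle)
#'
#' @param device a \code{liet_device} (its grating is ignored: uniform
#'   films are used).
#' @param lambda_nm wavelength (nm).
#' @param theta_rad polar angle(s) in the collection half-space.
#' @param z_frac dipole depth inside the barrier layer, 0 = Al side,
#'   1 = wire (Cr) side; default mid-plane.
#' @param from collection side: "superstrate" (through the wires into air,
#'   default) or "substrate" (through the Al film into glass).
#' @return complex far-field amplitude(s), arbitrary (but fixed) scale.
#' @export
dipole_farfield_direct <- function(device, lambda_nm, theta_rad,
                                   z_frac = 0.5, from = "superstrate") {
  mats <- device$materials
  epsv <- function(nm) permittivity(mats[[nm]], lambda_nm)
  eps_s <- epsv("Al2O3")
  k0 <- 2 * pi / lambda_nm
  d_bar <- device$barrier_thickness
  # "wire" side of the barrier: Cr, Au, optional overlayer, then air
  wire_layers <- list(list(eps = epsv("Cr"), d = device$adhesion_thickness),
                      list(eps = epsv("Au"), d = device$wire_thickness))
  if (!is.null(device$overlayer))
    wire_layers <- c(wire_layers,
                     list(list(eps = epsv(device$overlayer$material),
                               d = device$overlayer$thickness_nm)))
  wire_df <- data.frame(eps = sapply(wire_layers, `[[`, "eps"),
                        d_nm = sapply(wire_layers, `[[`, "d"))
  al_df <- data.frame(eps = epsv("Al"), d_nm = device$bottom_thickness)
  if (from == "superstrate") {
    out_df <- wire_df; eps_out <- epsv(device$superstrate)
    back_df <- al_df; eps_back <- epsv(device$substrate)
    t_out <- (1 - z_frac) * d_bar; t_back <- z_frac * d_bar
  } else {
    out_df <- al_df; eps_out <- epsv(device$substrate)
    back_df <- wire_df; eps_back <- epsv(device$superstrate)
    t_out <- z_frac * d_bar; t_back <- (1 - z_frac) * d_bar
  }
  n_out <- Re(sqrt(eps_out))
  vapply(theta_rad, function(th) {
    kx <- n_out * k0 * sin(th)
    kz_s <- .kz_branch(sqrt(eps_s * k0^2 - kx^2 + 0i))
    th_s <- asin(kx / (Re(sqrt(eps_s)) * k0))
    r_back <- tmm_solve(eps_s, back_df, eps_back, lambda_nm, th_s, "p")$r
    sol_out <- tmm_solve(eps_s, out_df, eps_out, lambda_nm, th_s, "p")
    rb <- r_back * exp(2i * kz_s * t_back)
    ro <- sol_out$r * exp(2i * kz_s * t_out)
    s_amp <- kx / kz_s
    D <- s_amp * (1 + rb) / (1 - rb * ro)
    hy_out <- D * exp(1i * kz_s * t_out) * sol_out$t
    cos(th) * hy_out / n_out
  }, complex(1))
}

#' Reciprocity-route far-field amplitude on the planar stack
#'
#' Sends a unit-E-amplitude p-polarized plane wave from the collection side
#' at the observation angle and returns Ez at the dipole position in the
#' barrier layer.
#'
#' @inheritParams dipole_farfield_direct
#' @return complex amplitude(s), proportional to
#'   [dipole_farfield_direct()] with one global constant.
#' @export
dipole_farfield_reciprocal <- function(device, lambda_nm, theta_rad,
                                       z_frac = 0.5,
                                       from = "superstrate") {
  stk <- device_planar_stack(device, lambda_nm, from = from)
  n_in <- Re(sqrt(stk$eps_in))
  # barrier region index in propagation order (region 1 = incidence
  # half-space): from glass it sits after Al; from air after
  # [overlayer], Au, Cr
  n_lay <- nrow(stk$layers)
  i_barrier <- if (from == "substrate") 2 else n_lay - 1
  # depth from the barrier's entry plane: Al side first when coming from
  # the substrate, Cr side first when coming from the superstrate
  z_entry <- if (from == "substrate") z_frac * device$barrier_thickness
             else (1 - z_frac) * device$barrier_thickness
  vapply(theta_rad, function(th) {
    sol <- tmm_solve(stk$eps_in, stk$layers, stk$eps_out, lambda_nm, th,
                     "p")
    f <- tmm_field_at(sol, region = i_barrier + 1, z_nm = z_entry)
    n_in * f$Ez   # incident Hy = n_in <=> unit E amplitude
  }, complex(1))
}
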
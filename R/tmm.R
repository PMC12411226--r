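## Transfer-matrix method (TMM) for planar multilayers.
##
## Serves two roles: reference solver for the homogeneous limit of the
## grating solver, and substrate for the buried-dipole reciprocity oracle.
##
## Conventions: exp(-i w t); the wave enters from the incidence half-space
## and travels towards positive z (stack listed in propagation order);
## kz = k0 sqrt(eps - eps_in sin^2 theta) with Im(kz) >= 0 (Re >= 0 if
## purely propagating). TM (p) fields are expressed through U = Hy and the
## normalized tangential field Sx = (kz / (k0 eps)) (a - b) so that the
## interface admittance is q = kz/(k0 eps) (TM) or q = kz/k0 (TE).

.kz_branch <- function(kz) {
  flip <- Im(kz) < 0 | (Im(kz) == 0 & Re(kz) < 0)
  kz[flip] <- -kz[flip]
  kz
}

#' Solve a planar multilayer at one wavelength and angle
#'
#' @param eps_in complex permittivity of the (lossless) incidence
#'   half-space.
#' @param layers data.frame with columns \code{eps} (complex) and \code{d_nm}
#'   (thickness); may have zero rows.
#' @param eps_out permittivity of the exit half-space.
#' @param lambda_nm vacuum wavelength (nm).
#' @param theta_rad incidence polar angle in the incidence medium.
#' @param pol "p" (TM) or "s" (TE).
#' @return list with complex \code{r}, \code{t} (field-amplitude ratios of
#'   Hy for p / Ey for s), power \code{R}, \code{Tr}, per-layer absorption
#'   \code{A_layers} from the analytic volume integral of the dissipation
#'   density, total \code{A}, per-layer coefficient matrix \code{amp}
#'   (columns a, b referenced at each layer's entry plane), \code{kz}
#'   (per region), \code{kx}, and a flag \code{evanescent_out}.
#' @export
tmm_solve <- function(eps_in, layers, eps_out, lambda_nm, theta_rad = 0,
                      pol = c("p", "s")) {
  pol <- match.arg(pol)
  k0 <- 2 * pi / lambda_nm
  eps_all <- c(eps_in, if (nrow(layers)) layers$eps else NULL, eps_out)
  d_all <- c(0, if (nrow(layers)) layers$d_nm else NULL, 0)
  kx <- k0 * sqrt(eps_in) * sin(theta_rad)
  kz <- .kz_branch(sqrt(eps_all * k0^2 - kx^2 + 0i))
  q <- if (pol == "p") kz / (k0 * eps_all) else kz / k0
  n_reg <- length(eps_all)
  # transfer: [a_{j+1}; b_{j+1}] = M_j [a_j; b_j], coefficients referenced
  # at each region's entry plane
  Ttot <- diag(2) + 0i
  Ms <- vector("list", n_reg - 1)
  for (j in seq_len(n_reg - 1)) {
    ph <- exp(1i * kz[j] * d_all[j])
    rq <- q[j] / q[j + 1]
    # a' = 0.5[(1+rq) ph a + (1-rq) ph^-1 b]; b' = 0.5[(1-rq) ph a + (1+rq) ph^-1 b]
    M <- 0.5 * matrix(c((1 + rq) * ph, (1 - rq) * ph,
                        (1 - rq) / ph, (1 + rq) / ph), 2, 2)
    Ms[[j]] <- M
    Ttot <- M %*% Ttot
  }
  r <- -Ttot[2, 1] / Ttot[2, 2]
  t <- Ttot[1, 1] + Ttot[1, 2] * r
  # back-fill amplitudes
  amp <- matrix(0i, n_reg, 2, dimnames = list(NULL, c("a", "b")))
  amp[1, ] <- c(1 + 0i, r)
  for (j in seq_len(n_reg - 1)) amp[j + 1, ] <- Ms[[j]] %*% amp[j, ]
  R <- Mod(r)^2
  Tr <- Mod(t)^2 * Re(q[n_reg]) / Re(q[1])
  # analytic per-layer dissipation integral, normalized to incident flux
  A_layers <- numeric(max(nrow(layers), 0))
  if (nrow(layers)) {
    for (j in seq_len(nrow(layers))) {
      reg <- j + 1
      a <- amp[reg, 1]; b <- amp[reg, 2]
      kzj <- kz[reg]; d <- d_all[reg]; epsj <- eps_all[reg]
      if (Im(epsj) == 0) next
      if (pol == "p") {
        # |Ex|^2 coefficients (q a, -q b); |Ez|^2 coefficients scaled kx/(k0 eps)
        qe <- kz[reg] / (k0 * epsj)
        ce <- kx / (k0 * epsj)
        I2 <- .int_two_wave(qe * a, -qe * b, kzj, d) +
              .int_two_wave(ce * a,  ce * b, kzj, d)
      } else {
        I2 <- .int_two_wave(a, b, kzj, d)
      }
      A_layers[j] <- 0.5 * k0 * Im(epsj) * I2 / (0.5 * Re(q[1]))
    }
  }
  list(r = r, t = t, R = R, Tr = Tr, A_layers = A_layers,
       A = sum(A_layers), amp = amp, kz = kz, kx = kx, q = q,
       eps = eps_all, d = d_all, k0 = k0,
       evanescent_out = Im(kz[n_reg]) > 0)
}

# integral over [0, d] of |A exp(i kz z) + B exp(-i kz z)|^2
.int_two_wave <- function(A, B, kz, d) {
  kp <- Re(kz); kpp <- Im(kz)
  i1 <- if (abs(kpp) > 1e-14) (1 - exp(-2 * kpp * d)) / (2 * kpp) else d
  i2 <- if (abs(kpp) > 1e-14) (exp(2 * kpp * d) - 1) / (2 * kpp) else d
  i3 <- if (abs(kp) > 1e-14) (exp(2i * kp * d) - 1) / (2i * kp) else d
  Mod(A)^2 * i1 + Mod(B)^2 * i2 + 2 * Re(A * Conj(B) * i3)
}

#' Field coefficients of a TMM solution at a depth inside a region
#'
#' @param sol result of [tmm_solve()].
#' @param region region index (1 = incidence half-space).
#' @param z_nm depth from that region's entry plane.
#' @return list(U, Sx, Ez) of normalized field components (U = Hy for p).
#' @export
tmm_field_at <- function(sol, region, z_nm) {
  a <- sol$amp[region, 1]; b <- sol$amp[region, 2]
  kz <- sol$kz[region]
  U <- a * exp(1i * kz * z_nm) + b * exp(-1i * kz * z_nm)
  qe <- kz / (sol$k0 * sol$eps[region])
  Sx <- qe * (a * exp(1i * kz * z_nm) - b * exp(-1i * kz * z_nm))
  Ez <- (sol$kx / (sol$k0 * sol$eps[region])) * U
  list(U = U, Sx = Sx, Ez = Ez)
}

#' Planar (grating-removed) permittivity stack of a device
#'
#' Replaces the Au/Cr wires by uniform films, keeping the rest of the
#' stack, listed in propagation order for the requested incidence side.
#'
#' @param device a \code{liet_device}.
#' @param lambda_nm wavelength (nm).
#' @param from "substrate" (glass-side incidence, the collection side) or
#'   "superstrate".
#' @return list(eps_in, layers, eps_out) ready for [tmm_solve()].
#' @export
device_planar_stack <- function(device, lambda_nm, from = c("substrate",
                                                            "superstrate")) {
  from <- match.arg(from)
  mats <- device$materials
  epsv <- function(nm) permittivity(mats[[nm]], lambda_nm)
  lays <- data.frame(
    eps = c(epsv(device$substrate) * 0 + 0i),
    d_nm = 0
  )[0, ]
  top <- list()
  if (!is.null(device$overlayer))
    top <- list(list(eps = epsv(device$overlayer$material),
                     d = device$overlayer$thickness_nm))
  seq_sup_to_sub <- c(top, list(
    list(eps = epsv("Au"), d = device$wire_thickness),
    list(eps = epsv("Cr"), d = device$adhesion_thickness),
    list(eps = epsv("Al2O3"), d = device$barrier_thickness),
    list(eps = epsv("Al"), d = device$bottom_thickness)
  ))
  if (from == "superstrate") {
    ord <- seq_sup_to_sub
    eps_in <- epsv(device$superstrate); eps_out <- epsv(device$substrate)
  } else {
    ord <- rev(seq_sup_to_sub)
    eps_in <- epsv(device$substrate); eps_out <- epsv(device$superstrate)
  }
  list(eps_in = eps_in,
       layers = data.frame(eps = sapply(ord, `[[`, "eps"),
                           d_nm = sapply(ord, `[[`, "d")),
       eps_out = eps_out)
}
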
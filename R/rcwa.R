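## Rigorous coupled-wave analysis (RCWA / Fourier modal method) for a
## 1D-periodic lamellar grating, TM (p) polarization.
##
## The device's doubly periodic mesh has a y-period >= 100 um, far beyond
## the wavelength, so the solver treats the structure as periodic in x and
## invariant in y. TM fields are expanded as
##   Hy(x, z) = sum_n U_n(z) exp(i kx_n x),  kx_n = kx0 + 2 pi n / P,
## and the permittivity products use Li's correct factorization rules for
## lamellar profiles: the Toeplitz matrix of the Fourier coefficients of
## eps for Ez (continuous field, discontinuous eps) and the inverse of the
## Toeplitz matrix of 1/eps for Ex (discontinuous field, continuous Dx).
## Layer eigenmodes obey d^2 U / dz^2 = k0^2 Omega U with
##   Omega = [[1/eps]]^-1 (K [[eps]]^-1 K - I),  K = diag(kx_n / k0),
## and mode constants gamma = sqrt(-eig(Omega)), Im(gamma) >= 0.
## Layers are chained with Redheffer star products of interface scattering
## matrices, keeping only bounded exponentials, which also yields interior
## mode amplitudes for near-field extraction in the tunnelling gap.

# Fourier coefficient of a centred lamellar profile (value v_wire on
# |x| < w/2, v_fill elsewhere), order m
.lamellar_coef <- function(v_wire, v_fill, w, P, m) {
  f <- w / P
  ifelse(m == 0, v_fill + (v_wire - v_fill) * f,
         (v_wire - v_fill) * f * sin(pi * m * f) / (pi * m * f))
}

.toeplitz_cplx <- function(coefs, N) {
  # coefs: function(m) for m in -(N-1)..(N-1)
  idx <- outer(seq_len(N), seq_len(N), "-")
  matrix(coefs(as.vector(idx)), N, N)
}

.gamma_branch <- function(g) {
  flip <- Im(g) < 0 | (abs(Im(g)) < 1e-12 & Re(g) < 0)
  g[flip] <- -g[flip]
  g
}

# Mode basis (W, V, gamma) of one layer at fixed kx_n/k0 vector kxr
.layer_modes <- function(layer, kxr, P) {
  N <- length(kxr)
  if (layer$kind == "uniform") {
    g <- .gamma_branch(sqrt(layer$eps - kxr^2 + 0i))
    W <- diag(N) + 0i
    V <- diag(g / layer$eps)
    list(W = W, V = V, gamma = g,
         Einv = diag(rep(1 / layer$eps, N)))
  } else {
    E  <- .toeplitz_cplx(function(m)
      .lamellar_coef(layer$eps_wire, layer$eps_fill, layer$w, P, m), N)
    Ai <- .toeplitz_cplx(function(m)
      .lamellar_coef(1 / layer$eps_wire, 1 / layer$eps_fill, layer$w, P, m),
      N)
    Einv <- solve(E)
    Omega <- solve(Ai, (kxr * Einv) * rep(kxr, each = N) - diag(N))
    eg <- eigen(Omega, symmetric = FALSE)
    g <- .gamma_branch(sqrt(-eg$values + 0i))
    W <- eg$vectors
    V <- (Ai %*% W) * rep(g, each = N)   # Ai W diag(g)
    list(W = W, V = V, gamma = g, Einv = Einv)
  }
}

# star(S, prop(x)) and star(prop(x), S) with diagonal phase vector x
.star_prop_right <- function(S, x) {
  list(S11 = S$S11, S12 = S$S12 * rep(x, each = nrow(S$S12)),
       S21 = x * S$S21, S22 = x * S$S22 * rep(x, each = nrow(S$S22)))
}
.star_prop_left <- function(x, S) {
  list(S11 = x * S$S11 * rep(x, each = nrow(S$S11)), S12 = x * S$S12,
       S21 = S$S21 * rep(x, each = nrow(S$S21)), S22 = S$S22)
}

.interface_smat <- function(m1, m2) {
  A <- solve(m2$W, m1$W)
  B <- solve(m2$V, m1$V)
  ApB <- A + B; AmB <- A - B
  G <- solve(ApB)
  S11 <- -G %*% AmB
  S12 <- 2 * G
  S21 <- 0.5 * (ApB - AmB %*% G %*% AmB)
  S22 <- AmB %*% G
  list(S11 = S11, S12 = S12, S21 = S21, S22 = S22)
}

.star <- function(A, B) {
  N <- nrow(A$S11)
  I <- diag(N) + 0i
  inv1 <- solve(I - B$S11 %*% A$S22)
  inv2 <- solve(I - A$S22 %*% B$S11)
  list(S11 = A$S11 + A$S12 %*% inv1 %*% B$S11 %*% A$S21,
       S12 = A$S12 %*% inv1 %*% B$S12,
       S21 = B$S21 %*% inv2 %*% A$S21,
       S22 = B$S22 + B$S21 %*% inv2 %*% A$S22 %*% B$S12)
}

#' Build the 1D-periodic solver stack of a device
#'
#' Propagation order is from the incidence side. For superstrate incidence
#' (the default, matching the collection geometry of the reciprocity
#' route) the order is air | optional analyte | Au wires | Cr wires |
#' Al2O3 | Al | glass. A finite-thickness overlayer fills the grating
#' grooves conformally from the groove floor up to its thickness and adds
#' a planar cap of the same thickness above the wires (see the methods
#' vignette for the rationale and limitations).
#'
#' @param device a \code{liet_device}.
#' @param lambda_nm wavelength (nm).
#' @param from incidence side, "superstrate" (default) or "substrate".
#' @return list(eps_in, layers, eps_out, P, i_gap, from) where
#'   \code{i_gap} is the index of the Al2O3 layer in \code{layers}.
#' @export
rcwa_stack <- function(device, lambda_nm,
                       from = c("superstrate", "substrate")) {
  from <- match.arg(from)
  mats <- device$materials
  epsv <- function(nm) permittivity(mats[[nm]], lambda_nm)
  P <- device$period_x
  w <- device$wire_width
  eps_sup <- epsv(device$superstrate)
  h_cr <- device$adhesion_thickness
  h_au <- device$wire_thickness
  grat <- list()
  if (is.null(device$overlayer)) {
    grat <- list(
      list(kind = "grating", eps_wire = epsv("Cr"), eps_fill = eps_sup,
           w = w, d = h_cr),
      list(kind = "grating", eps_wire = epsv("Au"), eps_fill = eps_sup,
           w = w, d = h_au))
  } else {
    eps_an <- epsv(device$overlayer$material)
    t_an <- device$overlayer$thickness_nm
    # conformal fill: analyte occupies the grooves up to height t_an above
    # the groove floor, air beyond; split the Cr and Au bands accordingly
    add <- function(lst, eps_wire, z0, z1) {
      if (z1 <= z0) return(lst)
      tcut <- min(max(t_an, z0), z1)
      if (tcut > z0)
        lst <- c(lst, list(list(kind = "grating", eps_wire = eps_wire,
                                eps_fill = eps_an, w = w, d = tcut - z0)))
      if (z1 > tcut)
        lst <- c(lst, list(list(kind = "grating", eps_wire = eps_wire,
                                eps_fill = eps_sup, w = w, d = z1 - tcut)))
      lst
    }
    grat <- add(grat, epsv("Cr"), 0, h_cr)
    grat <- add(grat, epsv("Au"), h_cr, h_cr + h_au)
    grat <- c(grat, list(list(kind = "uniform", eps = eps_an, d = t_an)))
  }
  lays_sub_up <- c(
    list(list(kind = "uniform", eps = epsv("Al"),
              d = device$bottom_thickness),
         list(kind = "uniform", eps = epsv("Al2O3"),
              d = device$barrier_thickness)),
    grat)
  if (from == "substrate") {
    list(eps_in = epsv(device$substrate), layers = lays_sub_up,
         eps_out = eps_sup, P = P, i_gap = 2, from = from)
  } else {
    lays <- rev(lays_sub_up)
    list(eps_in = eps_sup, layers = lays, eps_out = epsv(device$substrate),
         P = P, i_gap = length(lays) - 1, from = from)
  }
}

#' Solve the periodic structure at one wavelength and angle (TM)
#'
#' @param stack result of [rcwa_stack()] (or a hand-built equivalent).
#' @param lambda_nm vacuum wavelength (nm).
#' @param theta_rad polar incidence angle in the incidence half-space.
#' @param N number of Fourier harmonics (odd, >= 11 recommended).
#' @param field_layer optional index of a layer in which near-field mode
#'   amplitudes are returned (defaults to \code{stack$i_gap}).
#' @param pol polarization; only "p" (TM) is implemented, matching the
#'   polarization of the tunnelling dipoles.
#' @return list with \code{r}, \code{t} (complex order amplitudes of Hy for
#'   unit-E incident amplitude), \code{R_orders}, \code{T_orders},
#'   \code{Rtot}, \code{Ttot}, per-layer flux-based absorption
#'   \code{A_layers}, \code{Atot}, order index \code{orders}, in-plane
#'   wavevectors \code{kx}, and \code{field} (layer modes + amplitudes for
#'   [rcwa_gap_field()]).
#' @export
rcwa_solve <- function(stack, lambda_nm, theta_rad, N = 41,
                       field_layer = NULL, pol = "p") {
  if (pol != "p")
    stop("only p (TM) polarization is implemented: the tunnelling dipoles ",
         "are surface-normal and radiate p-polarized light")
  if (N %% 2 == 0) stop("N must be odd")
  if (is.null(field_layer)) field_layer <- stack$i_gap
  k0 <- 2 * pi / lambda_nm
  P <- stack$P
  n_in <- Re(sqrt(stack$eps_in))
  orders <- seq.int(-(N - 1) / 2, (N - 1) / 2)
  kxr <- n_in * sin(theta_rad) + orders * (lambda_nm / P)  # kx_n / k0
  lays <- stack$layers
  nl <- length(lays)
  modes_in <- .layer_modes(list(kind = "uniform", eps = stack$eps_in),
                           kxr, P)
  modes_out <- .layer_modes(list(kind = "uniform", eps = stack$eps_out),
                            kxr, P)
  ml <- lapply(lays, function(L) .layer_modes(L, kxr, P))
  Xl <- lapply(seq_len(nl), function(j)
    exp(1i * k0 * ml[[j]]$gamma * lays[[j]]$d))
  ifc <- vector("list", nl + 1)   # interface j-1 -> j (0 = incidence)
  prev <- modes_in
  for (j in seq_len(nl)) {
    ifc[[j]] <- .interface_smat(prev, ml[[j]])
    prev <- ml[[j]]
  }
  ifc[[nl + 1]] <- .interface_smat(prev, modes_out)
  # prefix SA[j]: incidence through the interface INTO layer j
  SA <- vector("list", nl)
  SA[[1]] <- ifc[[1]]
  if (nl > 1) for (j in 2:nl)
    SA[[j]] <- .star(.star_prop_right(SA[[j - 1]], Xl[[j - 1]]), ifc[[j]])
  # suffix SBp[j]: interface OUT of layer j through the exit
  SBp <- vector("list", nl)
  SBp[[nl]] <- ifc[[nl + 1]]
  if (nl > 1) for (j in (nl - 1):1)
    SBp[[j]] <- .star(ifc[[j + 1]],
                      .star_prop_left(Xl[[j + 1]], SBp[[j + 1]]))
  Stot <- .star(.star_prop_right(SA[[nl]], Xl[[nl]]), ifc[[nl + 1]])
  # incidence: unit E amplitude <=> Hy amplitude n_in, central order
  a_in <- rep(0i, N); a_in[(N + 1) / 2] <- n_in
  r <- Stot$S11 %*% a_in
  t <- Stot$S21 %*% a_in
  g_in <- modes_in$gamma; g_out <- modes_out$gamma
  q0 <- Re(g_in[(N + 1) / 2] / stack$eps_in)
  R_orders <- Mod(r / n_in)^2 * Re(g_in / stack$eps_in) / q0
  T_orders <- Mod(t / n_in)^2 * Re(g_out / stack$eps_out) / q0
  # interior amplitudes per layer: forward f at entry plane, backward b at
  # exit plane (all exponentials bounded)
  inc_flux <- 0.5 * q0 * n_in^2
  flux_at <- function(m, cf, cb) {
    U <- m$W %*% (cf + cb)
    S <- m$V %*% (cf - cb)
    0.5 * sum(Re(S * Conj(U)))
  }
  A_layers <- numeric(nl)
  f <- b <- NULL; X <- Xl[[field_layer]]
  for (j in seq_len(nl)) {
    Xj <- Xl[[j]]
    rhs <- SA[[j]]$S21 %*% a_in
    M <- SA[[j]]$S22 * rep(Xj, each = N)
    M <- M %*% (SBp[[j]]$S11 * rep(Xj, each = N))
    fj <- solve(diag(N) - M, rhs)
    bj <- SBp[[j]]$S11 %*% (Xj * fj)
    A_layers[j] <- (flux_at(ml[[j]], fj, Xj * bj) -
                    flux_at(ml[[j]], Xj * fj, bj)) / inc_flux
    if (j == field_layer) { f <- fj; b <- bj }
  }
  list(r = as.vector(r), t = as.vector(t),
       R_orders = R_orders, T_orders = T_orders,
       Rtot = sum(R_orders), Ttot = sum(T_orders),
       A_layers = A_layers, Atot = sum(A_layers),
       orders = orders, kx = kxr * k0, k0 = k0, N = N,
       field = list(layer = field_layer, modes = ml[[field_layer]],
                    X = X, f = as.vector(f), b = as.vector(b),
                    d = lays[[field_layer]]$d,
                    from = if (is.null(stack$from)) "superstrate"
                           else stack$from,
                    eps = if (lays[[field_layer]]$kind == "uniform")
                      lays[[field_layer]]$eps else NA))
}

#' Near-field Ez inside the field layer of an RCWA solution
#'
#' Reconstructs the surface-normal electric-field component at positions x
#' and a fractional depth inside the layer captured by
#' \code{rcwa_solve(..., field_layer=)} (by default the Al2O3 gap).
#'
#' @param sol result of [rcwa_solve()].
#' @param x_nm positions along x (wire centred at 0).
#' @param z_frac depth in the layer measured from the Al side (0 = Al
#'   interface, 1 = wire side), independent of the incidence side.
#' @return complex Ez values at \code{x_nm} (normalized to the unit-E
#'   incident amplitude).
#' @export
rcwa_gap_field <- function(sol, x_nm, z_frac = 0.5) {
  fd <- sol$field
  m <- fd$modes
  z <- if (identical(fd$from, "substrate")) z_frac * fd$d else
    (1 - z_frac) * fd$d
  ph_f <- exp(1i * sol$k0 * m$gamma * z)
  ph_b <- exp(1i * sol$k0 * m$gamma * (fd$d - z))
  U <- m$W %*% (fd$f * ph_f + fd$b * ph_b)
  # Ez = (1/eps) * kx/k0 * Hy; in Fourier space use the inverse-eps Toeplitz
  kxr <- sol$kx / sol$k0
  EzF <- fd$modes$Einv %*% (kxr * U)
  phase <- exp(1i * outer(x_nm, sol$kx, "*"))
  as.vector(phase %*% EzF)
}
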
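## Simmons tunnel-junction forward model, Fowler-Nordheim representation,
## and barrier-parameter fitting.
##
## Intermediate-voltage Simmons formula for a symmetric mean barrier of
## height phi (eV) and width ds (nm), with the effective-mass substitution
## m = m_eff * m_e (no image-force rounding):
##   J(V) = J0 [ (phi - V/2) exp(-a sqrt(phi - V/2))
##             - (phi + V/2) exp(-a sqrt(phi + V/2)) ],
##   a  = (2 ds / hbar) sqrt(2 m)  (evaluated in eV-nm units),
##   J0 = e / (2 pi h ds^2),
## valid for 0 < V < 2 phi. Beyond barrier collapse (V > 2 phi) the model
## switches to the Fowler-Nordheim field-emission branch with a message.

#' Simmons barrier parameters
#'
#' @param phi_ev mean barrier height (eV, > 0).
#' @param ds_nm barrier width (nm, > 0).
#' @param m_eff effective-mass ratio m/m_e in (0, 1]; default 0.23.
#' @return object of class \code{liet_barrier}.
#' @export
barrier_params <- function(phi_ev, ds_nm, m_eff = 0.23) {
  stopifnot(phi_ev > 0, ds_nm > 0, m_eff > 0, m_eff <= 1)
  structure(list(phi_ev = phi_ev, ds_nm = ds_nm, m_eff = m_eff),
            class = "liet_barrier")
}

#' Simmons current density
#'
#' Odd in V; |V| above the 5 V breakdown guard is rejected. For
#' |V| > 2 phi the field-emission branch is used (noted via message once
#' per call).
#'
#' @param V bias, volts (vectorized).
#' @param p a \code{liet_barrier} (or list with phi_ev, ds_nm, m_eff).
#' @return current density, A m^-2.
#' @export
#' @examples
#' p <- barrier_params(2.62, 3.2)
#' simmons_J(0, p)                      # 0
#' simmons_J(-0.5, p) + simmons_J(0.5, p)  # 0 (odd symmetry)
simmons_J <- function(V, p) {
  if (any(abs(V) > 5)) stop("bias beyond the 5 V breakdown guard")
  phi <- p$phi_ev; ds <- p$ds_nm; mr <- p$m_eff
  a <- 2 * ds * liet_constants$k_free_nm * sqrt(mr)   # 1/sqrt(eV)
  J0 <- liet_constants$e_C /
    (2 * pi * liet_constants$h_Js * (ds * 1e-9)^2)    # A m^-2 per eV
  s <- sign(V); v <- abs(V)
  J <- numeric(length(V))
  mid <- v < 2 * phi
  if (any(mid)) {
    b1 <- phi - v[mid] / 2; b2 <- phi + v[mid] / 2
    J[mid] <- J0 * (b1 * exp(-a * sqrt(b1)) - b2 * exp(-a * sqrt(b2)))
  }
  if (any(!mid)) {
    message("bias beyond barrier collapse (V > 2*phi = ",
            signif(2 * phi, 3), " V): using field-emission branch")
    # Fowler-Nordheim: J = C F^2 exp(-B phi^(3/2) / F), F = V / ds
    vf <- v[!mid]
    F_vnm <- vf / ds                                   # V / nm
    B <- (4 / 3) * liet_constants$k_free_nm * sqrt(mr) # 1/(eV^... ) nm V^-1
    # prefactor on the Simmons scale so the branches share one magnitude
    C0 <- J0 * phi
    J[!mid] <- C0 * (vf / (2 * phi))^2 * exp(-B * phi^1.5 / F_vnm)
  }
  s * J
}

#' Fowler-Nordheim transform of an I-V curve
#'
#' Maps a positive-branch curve to (1/V, ln(J/V^2)) and reports the
#' interior minimum (the direct-tunnelling / field-emission crossover)
#' with parabolic refinement, or its absence.
#'
#' @param iv data.frame with columns \code{V} and \code{J} (or an
#'   \code{iv_curve}).
#' @return list(fn = data.frame(inv_V, lnJV2), minimum = list(V, inv_V,
#'   lnJV2) or NULL, has_minimum).
#' @export
fn_transform <- function(iv) {
  V <- iv$V; J <- iv$J
  bad <- which(!(V > 0 & J > 0))
  if (length(bad))
    stop("nonpositive V or J on the analyzed branch at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  ord <- order(1 / V)
  x <- (1 / V)[ord]
  y <- log(J / V^2)[ord]
  i <- which.min(y)
  has_min <- i > 1 && i < length(y)
  minimum <- NULL
  if (has_min) {
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    den <- y0 - 2 * y1 + y2
    dx <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / den
    # local parabolic refinement on the (possibly non-uniform) 1/V axis
    h <- (x[i + 1] - x[i - 1]) / 2
    x_min <- x[i] + dx * h
    minimum <- list(V = 1 / x_min, inv_V = x_min,
                    lnJV2 = y1 - 0.25 * (y0 - y2) * dx)
  }
  list(fn = data.frame(inv_V = x, lnJV2 = y), minimum = minimum,
       has_minimum = has_min)
}

#' Fit the Simmons model to an I-V curve
#'
#' Least squares on ln(J) (the curve spans decades, so log residuals weight
#' the direct-tunnelling and field-emission regimes evenly) with bounded
#' parameters phi in [0.5, 5] eV, ds in [1, 8] nm and fixed effective mass.
#' A coarse grid search seeds L-BFGS-B so remote initial guesses converge.
#'
#' @param iv data.frame(V, J), V > 0 strictly increasing, >= 20 points.
#' @param m_eff fixed effective-mass ratio.
#' @param start initial guess c(phi_ev, ds_nm).
#' @param grid_search if TRUE (default) refine the start on a coarse grid
#'   first.
#' @return list(params = \code{liet_barrier}, residual_norm, cov (2x2
#'   parameter covariance from the Hessian), convergence, boundary
#'   (TRUE with a warning when the optimum sits on a bound), fit).
#' @export
fit_simmons <- function(iv, m_eff = 0.23, start = c(1.5, 5),
                        grid_search = TRUE) {
  V <- iv$V; J <- iv$J
  if (length(V) < 20) stop("need >= 20 points spanning both regimes")
  if (any(J <= 0)) stop("nonpositive current density in input")
  lo <- c(0.5, 1); hi <- c(5, 8)
  lnJ <- log(J)
  obj <- function(th) {
    Jm <- suppressMessages(simmons_J(V, list(phi_ev = th[1], ds_nm = th[2],
                                             m_eff = m_eff)))
    if (any(Jm <= 0)) return(1e10)
    sum((log(Jm) - lnJ)^2)
  }
  th0 <- pmin(pmax(start, lo), hi)
  if (grid_search) {
    gr <- expand.grid(phi = seq(lo[1], hi[1], length.out = 12),
                      ds = seq(lo[2], hi[2], length.out = 12))
    vals <- apply(gr, 1, obj)
    cand <- as.numeric(gr[which.min(vals), ])
    if (min(vals) < obj(th0)) th0 <- cand
  }
  fit <- stats::optim(th0, obj, method = "L-BFGS-B", lower = lo,
                      upper = hi, hessian = TRUE,
                      control = list(factr = 1e4, maxit = 500))
  if (fit$convergence != 0)
    stop("Simmons fit did not converge: ", fit$message)
  at_bound <- any(abs(fit$par - lo) < 1e-6) || any(abs(fit$par - hi) < 1e-6)
  if (at_bound)
    warning("fitted parameter at a bound; model mismatch likely (phi = ",
            signif(fit$par[1], 4), " eV, ds = ", signif(fit$par[2], 4),
            " nm)")
  n <- length(V)
  sigma2 <- fit$value / max(n - 2, 1)
  cov <- tryCatch(2 * sigma2 * solve(fit$hessian),
                  error = function(e) matrix(NA_real_, 2, 2))
  list(params = barrier_params(fit$par[1], fit$par[2], m_eff),
       residual_norm = sqrt(fit$value), cov = cov,
       convergence = fit$convergence, boundary = at_bound, fit = fit)
}
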
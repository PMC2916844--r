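# Fixed-point (bump-shape) equations of the reduced dynamics.
#
# With the bump angle gauged to psi0 = 0, a localized steady state with
# unit total modulation R = |zA| + |zB| has the rescaled profile
#   Phi(u, phi) = [ (1+mu)/2 cos(u + d v) + (1-mu)/2 cos(u - d v) - t0 ]_+,
#   v = phi - x_phi,  t0 = thr(size),
# and self-consistency requires
#   g1 = J_mod * (C_A + C_B) - 1  = 0   (total modulation)
#   g2 = J_mod * (C_A - C_B) - mu = 0   (map preference)
# where C_A, C_B are the first-harmonic overlaps of Phi with the two map
# coordinates. The amplitude then follows from the mean M of Phi:
#   amp = 1 / (J_inh * M - t0),
# positive and finite only for J_inh above the critical inhibition t0 / M
# (amplitude instability otherwise). The angular integrals are closed-form;
# only the integral over the distance coordinate is numerical (trapezoid).

shape_integrals <- function(size, mu, x_phi, d, n_phi = 257) {
  g <- phi_grid(n_phi)
  v <- g$phi - x_phi
  t0 <- size_to_threshold(size)
  Wu <- (1 + mu) / 2 * exp(-1i * d * v) + (1 - mu) / 2 * exp(1i * d * v)
  rho <- Mod(Wu)
  pm <- rectified_cosine_moments(rho, rep(-t0, length(rho)))
  dir <- ifelse(rho > 0, Wu / rho, 0 + 0i)
  M <- sum(g$w * pm$P0)
  HA <- sum(g$w * exp(1i * d * g$phi) * dir * pm$P1)
  HB <- sum(g$w * exp(-1i * d * g$phi) * dir * pm$P1)
  CA <- HA * exp(-1i * d * x_phi)
  CB <- HB * exp(+1i * d * x_phi)
  list(M = M, CA = Re(CA), CB = Re(CB),
       imbalance = c(Im(CA), Im(CB)), t0 = t0)
}

# integrand of the first-order (in mu) expansion of the map-preference
# equation around the mu = 0 branch; the double-ring branch exists where
# dr_gain > 1.
double_ring_gain <- function(size, d, J_mod, x_phi = 0, n_phi = 257) {
  g <- phi_grid(n_phi)
  v <- g$phi - x_phi
  t0 <- size_to_threshold(size)
  rho <- abs(cos(d * v))
  s2 <- numeric(length(rho))
  full <- t0 <= -rho
  part <- !full & t0 < rho
  s2[full] <- 0.5
  if (any(part)) {
    uc <- acos(pmin(1, pmax(-1, t0 / rho[part])))
    s2[part] <- (uc / 2 - sin(2 * uc) / 4) / pi
  }
  2 * J_mod * sum(g$w * sin(d * v)^2 * s2)
}

# solve the mu = 0 branch: J_mod * (C_A + C_B)(size) = 1, monotone in size
solve_shape_mu0 <- function(J_mod, d, x_phi = 0, n_phi = 257) {
  f <- function(s) {
    si <- shape_integrals(s, 0, x_phi, d, n_phi)
    J_mod * (si$CA + si$CB) - 1
  }
  if (f(pi) < 0) return(NA_real_)   # below the Turing threshold
  stats::uniroot(f, c(1e-8, pi), tol = 1e-12)$root
}

#' Solve the fixed-point equations of the reduced dynamics
#'
#' Finds a localized steady state of the order-parameter dynamics by Newton
#' iteration on the bump shape `(size, mu)` (with the bump angle gauged to
#' `psi0 = 0` and the distance-coordinate offset `x_phi` taken from `init`),
#' then computes the amplitude from the inhibition. Both signs of the map
#' preference are reachable by mirrored initial conditions `+/- mu`.
#'
#' @param params a [model_params()] object.
#' @param init an [order_params()] initial guess (its `mu` selects the
#'   branch; its `x_phi` is kept fixed during the solve).
#' @param n_phi quadrature resolution over the distance coordinate.
#' @param tol residual tolerance.
#' @return an [order_params()] fixed point with attributes `residual`,
#'   `M` (mean of the rescaled profile) and `J_inh_critical`. The amplitude
#'   is `Inf` (flagged by attribute `amplitude_unstable`) when the
#'   inhibition is below critical.
#' @export
solve_fixed_point <- function(params, init = order_params(1, pi / 2),
                              n_phi = 257, tol = 1e-11) {
  p <- params
  x_phi <- init$x_phi
  # total-modulation equation solved for the size at given map preference
  # (the left side is monotone increasing in the size)
  s_of_mu <- function(m) {
    f <- function(s) {
      si <- shape_integrals(s, m, x_phi, p$d, n_phi)
      p$J_mod * (si$CA + si$CB) - 1
    }
    if (f(pi) < 0) return(NA_real_)
    stats::uniroot(f, c(1e-8, pi), tol = tol)$root
  }
  # residual of the map-preference equation along the branch s = s(mu);
  # mu = 0 is always a root by symmetry, the double-ring branch is a
  # second root at |mu| > 0
  G <- function(m) {
    s <- s_of_mu(m)
    if (is.na(s)) return(NA_real_)
    si <- shape_integrals(s, m, x_phi, p$d, n_phi)
    p$J_mod * (si$CA - si$CB) - m
  }
  m <- 0
  if (p$d > 0 && abs(init$mu) > 1e-8) {
    sgn <- sign(init$mu)
    grid <- sgn * seq(0.05, 1, length.out = 20)
    vals <- vapply(grid, G, numeric(1))
    ok <- !is.na(vals)
    flip <- which(ok[-1] & ok[-length(ok)] &
                    sgn * vals[-1] <= 0 & sgn * vals[-length(vals)] > 0)
    if (length(flip) > 0) {
      m <- stats::uniroot(G, c(grid[flip[1]], grid[flip[1] + 1]),
                          tol = tol)$root
    } else if (ok[length(ok)] && sgn * vals[length(vals)] >= -1e-9 &&
               any(sgn * vals[ok] > 0)) {
      m <- sgn  # fully localized branch (exact at d = 1)
    }
  }
  s <- s_of_mu(m)
  if (is.na(s))
    stop("no localized fixed point: coupling below the Turing threshold")
  si <- shape_integrals(s, m, x_phi, p$d, n_phi)
  g <- c(p$J_mod * (si$CA + si$CB) - 1, p$J_mod * (si$CA - si$CB) - m)
  if (max(abs(g)) > 1e4 * tol)
    stop(sprintf("fixed-point solver did not converge (residual %.3g, %.3g)",
                 g[1], g[2]))
  J_inh_crit <- si$t0 / si$M
  denom <- p$J_inh * si$M - si$t0
  unstable <- denom <= 0
  amp <- if (unstable) Inf else 1 / denom
  op <- order_params(amp = if (unstable) 0 else amp, size = s, mu = m,
                     psi0 = 0, x_phi = x_phi)
  op$amp <- amp
  attr(op, "residual") <- max(abs(g))
  attr(op, "M") <- si$M
  attr(op, "J_inh_critical") <- J_inh_crit
  attr(op, "amplitude_unstable") <- unstable
  op
}
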
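# Independent oracles used across the suite. These deliberately avoid the
# package's semi-analytic quadrature path: brute-force quadrature via
# stats::integrate, dense grid operators, and direct simulation.

# classical single-map ring model (kernel J1 * cos) -------------------------
# bump half-width from the self-consistency 1 = J1 * <[cos u - cos d]_+ cos u>
ring_oracle_size <- function(J1) {
  f <- function(delta) {
    g <- stats::integrate(function(u) (cos(u) - cos(delta)) * cos(u),
                          -delta, delta, rel.tol = 1e-10)$value / (2 * pi)
    J1 * g - 1
  }
  stats::uniroot(f, c(1e-6, pi), tol = 1e-12)$root
}

# Turing threshold of the uniform state from a dense discretized linear
# operator (perturbation gain eigenvalue), built directly from the pairwise
# kernel on a product grid -- no harmonics shortcut.
field_operator_leading_eig <- function(params, n_theta = 24, n_phi = 25) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(-pi / 2, pi / 2, length.out = n_phi)
  w_ph <- rep(1, n_phi); w_ph[c(1, n_phi)] <- 0.5; w_ph <- w_ph / sum(w_ph)
  gr <- expand.grid(th = th, ph = ph)
  wt <- rep(w_ph, each = n_theta) / n_theta
  tA <- gr$th + params$d * gr$ph
  tB <- gr$th - params$d * gr$ph
  K <- params$J_mod * (cos(outer(tA, tA, "-")) + cos(outer(tB, tB, "-"))) -
    params$J_inh
  L <- (-diag(nrow(K)) + K * rep(wt, each = nrow(K))) / params$tau
  max(Re(eigen(L, only.values = TRUE)$values))
}

# brute-force 2-D quadrature of the rescaled-profile moments
brute_shape_moments <- function(size, mu, x_phi, d, n = 400) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ph <- seq(-pi / 2, pi / 2, length.out = n + 1)
  t0 <- cos(size)
  f <- outer(th, ph, function(u, phv) {
    v <- d * (phv - x_phi)
    pmax(cos(u) * cos(v) - mu * sin(u) * sin(v) - t0, 0)
  })
  wp <- rep(1, n + 1); wp[c(1, n + 1)] <- 0.5; wp <- wp / sum(wp)
  M <- sum(colMeans(f) * wp)
  CA <- sum((colMeans(f * cos(th)) * cos(d * ph) -
             colMeans(f * sin(th)) * sin(d * ph)) * wp)
  list(M = M, CAplusCB = 2 * CA)
}

relax_to_op <- function(op0, params, t_end = 150 * params$tau, ...) {
  tr <- ringmorph::integrate_mf(op0, params, NULL, t_end = t_end, ...)
  ringmorph:::moments_to_op(attr(tr, "moments")[nrow(tr), ], params)
}
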
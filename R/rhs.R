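# Right-hand side of the reduced (order-parameter) dynamics.
#
# The recurrent current at a point (theta, phi) of the neural manifold is
#   h = Re[ W(phi) * exp(-1i * theta) ] + b,
#   W(phi) = J_mod * zA * exp(-1i d phi) + J_mod * zB * exp(+1i d phi)
#            + eps * I0 * exp(1i xi) * exp(-1i a phi),
#   b = I0 - J_inh * m0,
# where `a` encodes which map the tuned input lives on. The moment dynamics
#   tau * dy/dt = -y + <[h]_+ * (1, e^{i theta_A}, e^{i theta_B})>
# is evaluated either with the angular moments done in closed form and a
# 1-D trapezoid over phi ("reduced", exact in theta), or by 2-D trapezoidal
# quadrature on a product grid ("grid", the brute-force reference).

input_field_W <- function(y, params, inp, phi) {
  p <- params
  zA <- complex(real = y[2], imaginary = y[3])
  zB <- complex(real = y[4], imaginary = y[5])
  W <- p$J_mod * (zA * exp(-1i * p$d * phi) + zB * exp(1i * p$d * phi))
  if (inp$eps > 0)
    W <- W + inp$eps * p$I0 * exp(1i * inp$xi) * exp(-1i * inp$a * phi)
  W
}

mf_rhs_moments <- function(y, params, input = NULL, t = 0, n_phi = 257) {
  p <- params
  inp <- resolve_input(input, t, p)
  g <- phi_grid(n_phi)
  W <- input_field_W(y, p, inp, g$phi)
  b <- p$I0 - p$J_inh * y[1]
  rho <- Mod(W)
  pm <- rectified_cosine_moments(rho, rep(b, length(rho)))
  dir <- ifelse(rho > 0, W / rho, 0 + 0i)
  m0_new <- sum(g$w * pm$P0)
  zA_new <- sum(g$w * exp(1i * p$d * g$phi) * dir * pm$P1)
  zB_new <- sum(g$w * exp(-1i * p$d * g$phi) * dir * pm$P1)
  (c(m0_new, Re(zA_new), Im(zA_new), Re(zB_new), Im(zB_new)) - y) / p$tau
}

mf_rhs_moments_grid <- function(y, params, input = NULL, t = 0,
                                n_theta = 256, n_phi = 129) {
  p <- params
  inp <- resolve_input(input, t, p)
  g <- phi_grid(n_phi)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  W <- input_field_W(y, p, inp, g$phi)
  b <- p$I0 - p$J_inh * y[1]
  # h[i, j] over (theta_i, phi_j); theta quadrature = periodic mean
  h <- outer(cos(theta), Re(W)) + outer(sin(theta), Im(W)) + b
  r <- pmax(h, 0)
  m_phi <- colMeans(r)
  cA <- colMeans(r * cos(theta)); sA <- colMeans(r * sin(theta))
  zpsi <- complex(real = cA, imaginary = sA)
  m0_new <- sum(g$w * m_phi)
  zA_new <- sum(g$w * exp(1i * p$d * g$phi) * zpsi)
  zB_new <- sum(g$w * exp(-1i * p$d * g$phi) * zpsi)
  (c(m0_new, Re(zA_new), Im(zA_new), Re(zB_new), Im(zB_new)) - y) / p$tau
}

#' Time derivatives of the order parameters
#'
#' Evaluates the right-hand side of the five-variable reduced dynamics at a
#' given state. With `eps = 0` the equations for `(amp, size, mu, x_phi)` do
#' not depend on `psi0` (the bump angle is a marginal direction of the
#' continuous attractor).
#'
#' @param op an [order_params()] state.
#' @param params a [model_params()] object.
#' @param input a [tuned_input()] specification (or `NULL` for none).
#' @param t time at which time-dependent inputs are resolved.
#' @param method `"reduced"` (angular moments in closed form, 1-D trapezoid
#'   over the distance coordinate) or `"grid"` (2-D trapezoidal quadrature).
#' @param n_phi,n_theta quadrature resolutions.
#' @return named numeric vector of the five derivatives.
#' @export
order_param_rhs <- function(op, params, input = NULL, t = 0,
                            method = c("reduced", "grid"),
                            n_phi = if (method == "reduced") 257 else 129,
                            n_theta = 256) {
  method <- match.arg(method)
  y <- op_to_moments(op, params)
  dy <- if (method == "reduced")
    mf_rhs_moments(y, params, input, t, n_phi = n_phi)
  else
    mf_rhs_moments_grid(y, params, input, t, n_theta = n_theta, n_phi = n_phi)
  push_forward_op(op, y, dy, params)
}

# chain rule from moment derivatives to order-parameter derivatives
push_forward_op <- function(op, y, dy, params) {
  p <- params
  zA <- complex(real = y[2], imaginary = y[3])
  zB <- complex(real = y[4], imaginary = y[5])
  dzA <- complex(real = dy[2], imaginary = dy[3])
  dzB <- complex(real = dy[4], imaginary = dy[5])
  RA <- Mod(zA); RB <- Mod(zB); R <- RA + RB
  if (R < .Machine$double.eps)
    stop("order-parameter derivatives are undefined at zero modulation")
  dRA <- Re(Conj(zA) * dzA) / max(RA, 1e-300)
  dRB <- Re(Conj(zB) * dzB) / max(RB, 1e-300)
  dphiA <- Im(Conj(zA) * dzA) / max(RA^2, 1e-300)
  dphiB <- Im(Conj(zB) * dzB) / max(RB^2, 1e-300)
  dR <- dRA + dRB
  damp <- p$J_mod * dR / p$I0
  dmu <- ((dRA - dRB) - op$mu * dR) / R
  dpsi0 <- (dphiA + dphiB) / 2
  dx_phi <- if (p$d > 0) (dphiA - dphiB) / (2 * p$d) else 0
  t0 <- size_to_threshold(op$size)
  dt0 <- p$J_inh * dy[1] / (p$I0 * op$amp) - t0 * damp / op$amp
  # d(size)/d(t0) on the three branches of the parametrisation
  dsize_dt0 <- if (op$size < 0 || op$size > pi) -1
               else -1 / max(sin(op$size), 1e-8)
  dsize <- dsize_dt0 * dt0
  c(amp = damp, size = dsize, mu = dmu, psi0 = dpsi0, x_phi = dx_phi)
}
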
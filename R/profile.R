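#' Steady-state activity profile
#'
#' Evaluates the threshold-linear steady-state activity determined by a set
#' of order parameters on a regular (middle-map angle x distance coordinate)
#' grid:
#' ```
#'   m(theta, phi) = I0 * amp * [ cos(theta - psi0) cos(d (phi - x_phi))
#'                     - mu sin(theta - psi0) sin(d (phi - x_phi))
#'                     - thr(size) ]_+
#' ```
#'
#' The activity is exactly zero outside the threshold region; the support
#' and shape depend only on `(size, mu, psi0, x_phi, d)` while the overall
#' amplitude scales linearly with the uniform input `I0`.
#'
#' @param op an [order_params()] state.
#' @param params a [model_params()] object.
#' @param grid list with `n_theta` and `n_phi` (each >= 16).
#' @return an object of class `rm_profile`: list with `grid_theta`,
#'   `grid_phi` and the `n_theta x n_phi` matrix `values`.
#' @export
steady_profile <- function(op, params, grid = list(n_theta = 128, n_phi = 65)) {
  stopifnot(grid$n_theta >= 16, grid$n_phi >= 16)
  theta <- seq(0, 2 * pi, length.out = grid$n_theta + 1)[-(grid$n_theta + 1)]
  phi <- seq(-PHI_HALF_WIDTH, PHI_HALF_WIDTH, length.out = grid$n_phi)
  vals <- outer(theta, phi, function(th, ph)
    profile_at(op, params, th, ph))
  structure(list(grid_theta = theta, grid_phi = phi, values = vals),
            class = "rm_profile")
}

#' @rdname steady_profile
#' @param theta,phi coordinates at which to evaluate the profile (vectors of
#'   equal length, or any shapes accepted by recycling).
#' @return `profile_at()` returns the activity values at the given points.
#' @export
profile_at <- function(op, params, theta, phi) {
  t0 <- size_to_threshold(op$size)
  u <- theta - op$psi0
  v <- params$d * (phi - op$x_phi)
  f <- cos(u) * cos(v) - op$mu * sin(u) * sin(v)
  params$I0 * op$amp * pmax(f - t0, 0)
}

#' Evaluate the current-based activity at neuron labels
#'
#' Computes the instantaneous rectified current (i.e. the firing rate in the
#' threshold-linear model) at each neuron's label coordinates, given a
#' moment state and the external input. Used to turn mean-field trajectories
#' into per-neuron responses.
#' @noRd
rates_at_labels <- function(y, params, labels, input = NULL, t = 0) {
  p <- params
  inp <- resolve_input(input, t, p)
  W <- input_field_W(y, p, inp, labels$phi)
  b <- p$I0 - p$J_inh * y[1]
  h <- Re(W * exp(-1i * labels$theta_mid)) + b
  pmax(h, 0)
}
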
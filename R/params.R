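#' Model parameters
#'
#' Constitutive parameters of the two-map ring network.
#'
#' @param d map distance in `[0, 1]` (0 = identical maps, 1 = uncorrelated).
#' @param J_mod amplitude of the map-specific (cosine) coupling, per map.
#'   The full connection strength between neurons i and j is
#'   `J_mod * (cos(theta_A_i - theta_A_j) + cos(theta_B_i - theta_B_j)) - J_inh`
#'   (scaled by 1/N in the finite network).
#' @param J_inh uniform inhibition strength (> -1 for a finite homogeneous
#'   state; the localized states need more, see [amplitude_boundary()]).
#' @param I0 uniform external current (> 0). Changing `I0` rescales the
#'   activity but leaves all order parameters unchanged.
#' @param eps tuned-input amplitude as a fraction of `I0` (>= 0).
#' @param tau rate time constant; all times in the package are in the same
#'   unit (default 10, i.e. milliseconds for a 10 ms membrane-like constant).
#' @param sigma_noise white-noise amplitude added to the input current in
#'   noisy (current-based) simulations; 0 = deterministic.
#' @return an object of class `rm_params` (a validated named list).
#' @examples
#' p <- model_params(d = 0.4, J_mod = 10, J_inh = 6)
#' @export
model_params <- function(d, J_mod, J_inh, I0 = 1, eps = 0, tau = 10,
                         sigma_noise = 0) {
  check_d(d)
  stopifnot(J_mod >= 0, I0 > 0, eps >= 0, tau > 0, sigma_noise >= 0)
  structure(list(d = d, J_mod = J_mod, J_inh = J_inh, I0 = I0, eps = eps,
                 tau = tau, sigma_noise = sigma_noise),
            class = "rm_params")
}

#' @export
print.rm_params <- function(x, ...) {
  cat("ringmorph model parameters\n")
  cat(sprintf("  d = %g, J_mod = %g, J_inh = %g\n", x$d, x$J_mod, x$J_inh))
  cat(sprintf("  I0 = %g, eps = %g, tau = %g, sigma_noise = %g\n",
              x$I0, x$eps, x$tau, x$sigma_noise))
  invisible(x)
}

#' Order parameters of the reduced dynamics
#'
#' The mean-field dynamics closes exactly on five macroscopic variables,
#' equivalent to the mean activity and the first circular harmonic of the
#' activity in each of the two stored maps (two complex numbers and a real
#' one). In dimensionless form these are:
#'
#' * `amp`  -- amplitude scale of the activity profile, in units of the
#'   uniform input `I0` (so it is invariant under rescaling `I0`);
#' * `size` -- bump size: the angular half-width of the region of positive
#'   activity along the middle-map angle (at the bump's distance-coordinate
#'   center). `size <= 0` means no activity; `size = pi` (or beyond) means
#'   the whole network is active;
#' * `mu`   -- map preference in `[-1, 1]`; `+1`/`-1` = activity localized
#'   purely in map A / map B, `0` = both maps represented equally;
#' * `psi0` -- bump angle on the middle map, in `[0, 2*pi)`;
#' * `x_phi`-- bump offset along the distance coordinate.
#'
#' The steady-state activity profile determined by these variables is
#' `m(theta, phi) = I0 * amp * [F - thr(size)]_+` with
#' `F = cos(theta - psi0) cos(d (phi - x_phi))
#'      - mu sin(theta - psi0) sin(d (phi - x_phi))`,
#' see [steady_profile()].
#'
#' @param amp amplitude scale (>= 0), in units of `I0`.
#' @param size bump-size parameter (see above).
#' @param mu map preference in `[-1, 1]`.
#' @param psi0 bump angle on the middle map (radians).
#' @param x_phi bump offset along the distance coordinate.
#' @return an object of class `rm_op`.
#' @export
order_params <- function(amp, size, mu = 0, psi0 = 0, x_phi = 0) {
  stopifnot(amp >= 0, mu >= -1, mu <= 1)
  structure(list(amp = amp, size = size, mu = mu,
                 psi0 = wrap_angle(psi0), x_phi = x_phi),
            class = "rm_op")
}

#' @export
print.rm_op <- function(x, ...) {
  cat(sprintf(
    "order parameters: amp = %.4g, size = %.4g, mu = %.4g, psi0 = %.4g, x_phi = %.4g\n",
    x$amp, x$size, x$mu, x$psi0, x$x_phi))
  invisible(x)
}

#' @rdname order_params
#' @param op an `rm_op` object.
#' @export
as_vector_op <- function(op) {
  c(amp = op$amp, size = op$size, mu = op$mu, psi0 = op$psi0,
    x_phi = op$x_phi)
}

# threshold parametrisation of the bump size ---------------------------------
# The profile is amp * [F - t0]_+ with t0 the threshold. On [0, pi] the size
# is the half-width delta with t0 = cos(delta); the parametrisation is
# extended monotonically outside that range so that a profile below
# threshold everywhere (t0 > 1) maps to size < 0 and a profile strictly
# above threshold everywhere (t0 < -1) maps to size > pi.
size_to_threshold <- function(size) {
  ifelse(size < 0, 1 - size,
         ifelse(size > pi, -1 - (size - pi), cos(size)))
}

threshold_to_size <- function(t0) {
  ifelse(t0 > 1, 1 - t0,
         ifelse(t0 < -1, pi + (-1 - t0), acos(pmin(1, pmax(-1, t0)))))
}
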
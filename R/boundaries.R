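# Closed-form and semi-analytic phase boundaries in the
# (coupling, map-distance) plane.

#' Homogeneous/bump (Turing) boundary
#'
#' Critical map-specific coupling above which the spatially uniform state
#' destabilises into a localized bump:
#' `J_c(d) = 2 / (1 + sinc(pi d))` with `sinc(x) = sin(x)/x`. At `d = 0`
#' this reduces to the classical single-ring Turing threshold (the two
#' stored maps coincide and their cosine kernels add coherently); at `d = 1`
#' the maps are uncorrelated and the threshold doubles.
#'
#' @param d map distance in `[0, 1]` (vectorised).
#' @return critical coupling `J_mod`.
#' @export
homogeneous_boundary <- function(d) {
  vapply(d, check_d, numeric(1))
  g <- ifelse(d == 0, 1, sin(pi * d) / (pi * d))
  2 / (1 + g)
}

#' Critical inhibition (amplitude instability boundary)
#'
#' For a localized bump of given shape, the steady amplitude is
#' `1 / (J_inh * M - thr(size))` with `M` the mean of the rescaled profile;
#' it is positive and finite only for `J_inh > thr(size) / M`. Below that
#' critical inhibition the activity grows without bound. In the
#' homogeneous limit (`size = pi`) the critical value is exactly `-1`
#' (the uniform coupling must exceed `-1`).
#'
#' @param params a [model_params()] object; its `J_inh` is ignored.
#' @param shape optional [order_params()] giving the bump shape
#'   `(size, mu, x_phi)`; when `NULL` the shape is solved from `params`.
#' @param n_phi quadrature resolution.
#' @return the critical inhibition `J_inh`.
#' @export
amplitude_boundary <- function(params, shape = NULL, n_phi = 257) {
  if (is.null(shape)) {
    s <- solve_shape_mu0(params$J_mod, params$d, n_phi = n_phi)
    if (is.na(s)) return(-1)  # homogeneous regime: uniform state bound
    shape <- order_params(1, s)
  }
  si <- shape_integrals(shape$size, shape$mu, shape$x_phi, params$d, n_phi)
  si$t0 / si$M
}

#' Onset of the double-ring solution
#'
#' The map-preference equation, expanded to first order in `mu` around the
#' symmetric branch, yields a gain integral; the `mu != 0` (double-ring)
#' branch exists where the gain exceeds one. For distances below a cutoff
#' (maps too correlated) the gain never reaches one and there is no
#' double-ring onset (`NA` is returned).
#'
#' @param d map distance in `[0, 1]`.
#' @param J_max upper end of the coupling range scanned.
#' @param n_phi quadrature resolution.
#' @return the critical coupling at which the double-ring branch appears,
#'   or `NA` if it does not exist at this distance.
#' @export
double_ring_onset <- function(d, J_max = 30, n_phi = 257) {
  check_d(d)
  f <- function(J) {
    s <- solve_shape_mu0(J, d, n_phi = n_phi)
    if (is.na(s)) return(-1)
    double_ring_gain(s, d, J, n_phi = n_phi) - 1
  }
  J_lo <- homogeneous_boundary(d) + 1e-6
  Js <- seq(J_lo, J_max, length.out = 120)
  vals <- vapply(Js, f, numeric(1))
  ix <- which(vals[-1] > 0 & vals[-length(vals)] <= 0)
  if (length(ix) == 0) {
    if (vals[1] > 0) return(J_lo)
    return(NA_real_)
  }
  stats::uniroot(f, c(Js[ix[1]], Js[ix[1] + 1]), tol = 1e-10)$root
}

# upper edge of the double-ring region (gain drops back below one), used by
# the classifier via the gain itself; exported for scans
#' @rdname double_ring_onset
#' @param J_mod coupling at which to evaluate the existence gain.
#' @return `double_ring_exists()` returns TRUE where the mu != 0 branch
#'   exists (gain > 1).
#' @export
double_ring_exists <- function(J_mod, d, n_phi = 257) {
  s <- solve_shape_mu0(J_mod, d, n_phi = n_phi)
  if (is.na(s)) return(FALSE)
  double_ring_gain(s, d, J_mod, n_phi = n_phi) > 1
}

#' Onset of the cylinder solution
#'
#' The bump becomes free to move along the distance coordinate when its
#' support no longer touches the boundary of the admissible interval:
#' the activity is exactly zero at `phi = +/- pi/2` when
#' `size = d * pi / 2`. Since the bump size decreases with coupling, the
#' cylinder regime occupies `J_mod` above the returned critical value.
#'
#' @param d map distance in `(0, 1]`.
#' @param J_max upper end of the coupling search bracket.
#' @param n_phi quadrature resolution.
#' @return critical coupling, or `NA` when `d = 0` (no cylinder regime).
#' @export
cylinder_boundary <- function(d, J_max = 200, n_phi = 257) {
  check_d(d)
  if (d == 0) return(NA_real_)
  target <- d * pi / 2
  f <- function(J) {
    s <- solve_shape_mu0(J, d, n_phi = n_phi)
    if (is.na(s)) return(pi - target)
    s - target
  }
  if (f(J_max) > 0) return(NA_real_)
  stats::uniroot(f, c(homogeneous_boundary(d) + 1e-6, J_max), tol = 1e-10)$root
}
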
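#' Classify the operating regime of a parameter point
#'
#' Combines the analytic boundaries into a single label:
#' * `homogeneous` -- coupling below the Turing boundary; uniform activity.
#' * `single_ring` -- localized symmetric bump (`mu = 0`), pinned at
#'   `x_phi = 0` because its support spans the whole distance coordinate.
#' * `double_ring` -- pair of mirror solutions `+/- mu` localized in one map.
#' * `cylinder` -- symmetric bump whose support fits inside the distance
#'   coordinate, making `x_phi` marginal along a sub-segment.
#' * `amplitude_unstable` -- inhibition below the critical value for the
#'   bump shape (or below -1 in the homogeneous regime).
#'
#' @param params a [model_params()] object.
#' @param tol_mu threshold on `|mu|` for calling a solution double-ring.
#' @param n_phi quadrature resolution.
#' @return an object of class `rm_regime`: list with `label`, `op` (the
#'   regime's fixed point, where applicable) and `diagnostics` (boundary
#'   margins and the marginality probe).
#' @export
classify_regime <- function(params, tol_mu = 1e-3, n_phi = 257) {
  p <- params
  out <- function(label, op = NULL, diag = list()) {
    structure(list(label = label, op = op,
                   diagnostics = diag, params = p), class = "rm_regime")
  }
  J_hom <- homogeneous_boundary(p$d)
  if (p$J_mod <= J_hom) {
    lab <- if (p$J_inh <= -1) "amplitude_unstable" else "homogeneous"
    return(out(lab, diag = list(J_hom = J_hom,
                                margin_hom = J_hom - p$J_mod)))
  }
  s0 <- solve_shape_mu0(p$J_mod, p$d, n_phi = n_phi)
  gain <- double_ring_gain(s0, p$d, p$J_mod, n_phi = n_phi)
  dring <- gain > 1
  fp <- if (dring)
    solve_fixed_point(p, order_params(1, s0, mu = 0.5), n_phi = n_phi)
  else
    solve_fixed_point(p, order_params(1, s0, mu = 0), n_phi = n_phi)
  diag <- list(J_hom = J_hom, size_mu0 = s0, dr_gain = gain,
               J_inh_critical = attr(fp, "J_inh_critical"),
               cyl_size_target = p$d * pi / 2)
  if (attr(fp, "amplitude_unstable"))
    return(out("amplitude_unstable", fp, diag))
  if (dring && abs(fp$mu) > tol_mu)
    return(out("double_ring", fp, diag))
  if (p$d > 0 && s0 < p$d * pi / 2) {
    # marginality probe: a small offset along the distance coordinate must
    # feel no restoring drift while the bump stays inside the segment
    probe <- fp
    probe$x_phi <- 0.5 * (pi / 2 - s0 / p$d)
    drift <- order_param_rhs(probe, p, n_phi = n_phi)[["x_phi"]]
    diag$xphi_drift <- drift
    return(out("cylinder", fp, diag))
  }
  out("single_ring", fp, diag)
}

#' @export
print.rm_regime <- function(x, ...) {
  cat("regime:", x$label, "\n")
  if (!is.null(x$op)) print(x$op)
  invisible(x)
}

#' Scan the (distance, coupling) plane
#'
#' Classifies every node of a regular grid in `(d, J_mod)` at fixed
#' inhibition, reproducing the phase-diagram topology: homogeneous at weak
#' coupling; single ring at high correlation; double ring in a
#' low-correlation pocket; cylinder at strong coupling for all distances.
#'
#' @param d_range,J_range numeric length-2 ranges for distance and coupling.
#' @param resolution number of grid nodes per axis (scalar or length 2).
#' @param params_base a [model_params()] giving the remaining parameters.
#' @param n_phi quadrature resolution.
#' @return a long-format data frame with columns
#'   `d, J_mod, label, amp, size, mu`.
#' @export
scan_phase_diagram <- function(d_range = c(0, 1), J_range = c(0.5, 12),
                               resolution = 40, params_base = NULL,
                               n_phi = 129) {
  if (is.null(params_base)) params_base <- model_params(0, 1, 5)
  resolution <- rep(resolution, length.out = 2)
  ds <- seq(d_range[1], d_range[2], length.out = resolution[1])
  Js <- seq(J_range[1], J_range[2], length.out = resolution[2])
  rows <- vector("list", length(ds) * length(Js))
  i <- 0
  for (d in ds) for (J in Js) {
    i <- i + 1
    p <- params_base; p$d <- d; p$J_mod <- J
    reg <- classify_regime(p, n_phi = n_phi)
    op <- reg$op
    rows[[i]] <- data.frame(
      d = d, J_mod = J, label = reg$label,
      amp = if (is.null(op)) NA_real_ else op$amp,
      size = if (is.null(op)) NA_real_ else op$size,
      mu = if (is.null(op)) NA_real_ else op$mu)
  }
  do.call(rbind, rows)
}
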
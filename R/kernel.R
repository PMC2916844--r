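#' Coupling kernels for two-map and full-morph storage
#'
#' Returns the (mean-field) synaptic kernel as a function of two label
#' sets. In `two_maps` mode the kernel is the sum of the two per-map cosine
#' terms minus the uniform inhibition,
#' `J_mod (cos(dtheta_A) + cos(dtheta_B)) - J_inh`. In `full_morph` mode the
#' continuum of morph maps between two uncorrelated references is stored;
#' integrating the per-map cosine over the morph index gives exactly
#' `2 J_mod cos(dpsi) sinc(dphi) - J_inh` (with `dphi` the difference of
#' the distance coordinates at reference distance 1). The leading term of
#' the sinc factor's expansion matches a two-map kernel at the equivalent
#' distance [MORPH_EQUIV_D].
#'
#' @param params a [model_params()] object (`J_mod`, `J_inh`, `d` used).
#' @param mode `"two_maps"` or `"full_morph"`.
#' @param d_pair_equiv optional override of the map distance used by the
#'   `two_maps` kernel (e.g. [MORPH_EQUIV_D] to build the first-order
#'   approximant of the full-morph kernel).
#' @return a vectorised function `(labels_i, labels_j) -> coupling value`,
#'   where each argument is an `rm_labels` (rows are recycled against each
#'   other elementwise).
#' @export
morph_coupling_kernel <- function(params, mode = c("two_maps", "full_morph"),
                                  d_pair_equiv = NULL) {
  mode <- match.arg(mode)
  p <- params
  if (mode == "two_maps") {
    d_use <- if (is.null(d_pair_equiv)) p$d else d_pair_equiv
    function(li, lj) {
      dpsi <- li$theta_mid - lj$theta_mid
      dphi <- li$phi - lj$phi
      2 * p$J_mod * cos(dpsi) * cos(d_use * dphi) - p$J_inh
    }
  } else {
    function(li, lj) {
      dpsi <- li$theta_mid - lj$theta_mid
      dphi <- li$phi - lj$phi
      s <- ifelse(abs(dphi) < 1e-12, 1, sin(dphi) / dphi)
      2 * p$J_mod * cos(dpsi) * s - p$J_inh
    }
  }
}
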
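#' Parameter presets for the four operating regimes
#'
#' Desk-scale exemplars of each region of the phase diagram, used by the
#' fixture generator and throughout the examples and tests. The cylinder
#' preset uses a strong coupling so that the bump is small compared to the
#' admissible range of the distance coordinate, which is the condition for
#' clean dynamical pattern separation.
#'
#' @param which preset name: `"homogeneous"`, `"single_ring"`,
#'   `"double_ring"`, `"cylinder"`, `"cylinder_weak"` (larger bump),
#'   `"cylinder_task"` (bump nearly filling the distance coordinate, the
#'   geometry used for the delayed shortest-path task, where the offset
#'   flip threshold per stimulus step must be small),
#'   `"amplitude_unstable"`, or `"fig9_scan"` (base point of the
#'   coupling scan crossing double ring, single ring and cylinder).
#' @return a [model_params()] object.
#' @export
regime_presets <- function(which = c("homogeneous", "single_ring",
                                     "double_ring", "cylinder",
                                     "cylinder_weak", "cylinder_task",
                                     "amplitude_unstable", "fig9_scan")) {
  which <- match.arg(which)
  switch(which,
    homogeneous = model_params(d = 0.5, J_mod = 1.0, J_inh = 5),
    single_ring = model_params(d = 0.2, J_mod = 3.0, J_inh = 5),
    double_ring = model_params(d = 1.0, J_mod = 2.5, J_inh = 2),
    cylinder = model_params(d = 0.8, J_mod = 50, J_inh = 80, eps = 0.3),
    cylinder_weak = model_params(d = 0.8, J_mod = 20, J_inh = 30,
                                 eps = 0.15),
    cylinder_task = model_params(d = 0.5, J_mod = 22, J_inh = 40,
                                 eps = 0.2),
    amplitude_unstable = model_params(d = 0.2, J_mod = 6.0, J_inh = 2),
    fig9_scan = model_params(d = 0.95, J_mod = 3.0, J_inh = 8))
}
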
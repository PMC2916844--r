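#' @title Correlated map pairs on the ring
#'
#' @description
#' Two correlated maps are built from a "middle" map and an auxiliary
#' distance coordinate. Each neuron carries a middle-map angle `theta_mid`,
#' uniform on the circle, and a distance coordinate `phi`, uniform on the
#' symmetric interval `[-PHI_HALF_WIDTH, PHI_HALF_WIDTH]`. Its angles on the
#' two stored maps are then
#'
#'   theta_A = theta_mid + d * phi,   theta_B = theta_mid - d * phi,
#'
#' with `d` in `[0, 1]` the map distance: `d = 0` gives identical maps,
#' `d = 1` uncorrelated maps. The two map angles can differ by at most
#' `2 * d * PHI_HALF_WIDTH = d * pi` along the shortest arc.
#'
#' @name geometry
NULL

#' Half-width of the admissible interval of the distance coordinate
#'
#' The auxiliary coordinate `phi` is uniform on `[-pi/2, pi/2]`; at map
#' distance `d = 1` the map angles `theta_mid +/- phi` then differ by up to
#' `pi`, i.e. the full shortest-arc range, which is what makes the two maps
#' exactly uncorrelated in that limit.
#' @export
PHI_HALF_WIDTH <- pi / 2

#' Map-distance equivalent of storing a full morph sequence
#'
#' Storing the continuum of maps morphed between two uncorrelated rings
#' yields, after integrating the per-map cosine kernels over the morph
#' index, a coupling `cos(dpsi) * sin(dphi)/dphi`. Matching its quadratic
#' term in `dphi` with the two-map kernel factor `cos(d * dphi)` gives the
#' first-order equivalent two-map distance `1/sqrt(3)`.
#' @seealso [morph_coupling_kernel()]
#' @export
MORPH_EQUIV_D <- 1 / sqrt(3)

#' Sample a pair of correlated ring maps
#'
#' @param n_neurons number of neurons (>= 1).
#' @param d map distance in `[0, 1]` (0 = identical maps, 1 = uncorrelated).
#' @param seed integer seed; sampling is reproducible given the seed.
#' @return an object of class `rm_labels`: a data frame with columns
#'   `theta_mid`, `phi`, `theta_A`, `theta_B` and attribute `d`.
#' @examples
#' lab <- sample_correlated_maps(100, d = 0.5, seed = 1)
#' max(circ_dist(lab$theta_A, lab$theta_B)) <= 0.5 * pi
#' @export
sample_correlated_maps <- function(n_neurons, d, seed = NULL) {
  if (length(n_neurons) != 1L || n_neurons < 1 || n_neurons != round(n_neurons))
    stop("`n_neurons` must be a positive integer")
  check_d(d)
  if (!is.null(seed)) {
    old <- rng_save(); on.exit(rng_restore(old))
    set.seed(as.integer(seed))
  }
  theta_mid <- stats::runif(n_neurons, 0, 2 * pi)
  phi <- stats::runif(n_neurons, -PHI_HALF_WIDTH, PHI_HALF_WIDTH)
  neuron_labels(theta_mid, phi, d)
}

#' Build labels from given coordinates
#'
#' @param theta_mid angles on the middle map (wrapped to `[0, 2*pi)`).
#' @param phi distance coordinates in `[-pi/2, pi/2]`.
#' @param d map distance in `[0, 1]`.
#' @return an `rm_labels` data frame.
#' @export
neuron_labels <- function(theta_mid, phi, d) {
  check_d(d)
  stopifnot(length(theta_mid) == length(phi))
  if (any(abs(phi) > PHI_HALF_WIDTH + 1e-12))
    stop("`phi` outside the admissible interval [-pi/2, pi/2]")
  out <- data.frame(
    theta_mid = wrap_angle(theta_mid),
    phi = phi,
    theta_A = wrap_angle(theta_mid + d * phi),
    theta_B = wrap_angle(theta_mid - d * phi)
  )
  attr(out, "d") <- d
  class(out) <- c("rm_labels", "data.frame")
  out
}

check_d <- function(d) {
  if (length(d) != 1L || is.na(d) || d < 0 || d > 1)
    stop("map distance `d` must be a single value in [0, 1]")
  invisible(d)
}

#' Invert the map construction
#'
#' Recovers the middle-map angle and the distance coordinate from a pair of
#' map angles. The oriented difference `theta_A - theta_B` is taken along
#' the shortest arc (branch cut at exactly `pi`, broken toward the CCW arc),
#' which is the convention that makes morphing follow the shortest path.
#'
#' @param theta_A,theta_B angles on the two maps (radians).
#' @param d map distance in `(0, 1]`.
#' @return a list with components `theta_mid` and `phi`.
#' @export
inverse_transform <- function(theta_A, theta_B, d) {
  check_d(d)
  if (d == 0) {
    if (any(circ_dist(theta_A, theta_B) > 1e-10))
      stop("inconsistent pair: d = 0 but theta_A != theta_B")
    return(list(theta_mid = wrap_angle(theta_A),
                phi = rep(0, length(theta_A))))
  }
  delta <- circ_dist_signed(theta_B, theta_A)  # theta_A - theta_B, shortest
  phi <- delta / (2 * d)
  if (any(abs(phi) > PHI_HALF_WIDTH + 1e-9))
    stop("pair not representable at this map distance `d`")
  # middle map sits halfway along the same (shortest) arc
  theta_mid <- wrap_angle(theta_B + delta / 2)
  list(theta_mid = theta_mid, phi = phi)
}

#' Coordinates along the morph sequence
#'
#' Each neuron rotates from its map-A angle (`t = 0`) to its map-B angle
#' (`t = 1`) linearly in arc length along the shortest arc between the two,
#' which in middle-map coordinates is `theta_mid + (1 - 2 t) * d * phi`.
#'
#' @param labels an `rm_labels` object.
#' @param t morph index in `[0, 1]`.
#' @return vector of angles on the intermediate map.
#' @export
morph_coordinates <- function(labels, t) {
  stopifnot(inherits(labels, "rm_labels"))
  if (length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("morph index `t` must be a single value in [0, 1]")
  d <- attr(labels, "d")
  wrap_angle(labels$theta_mid + (1 - 2 * t) * d * labels$phi)
}

#' Build a full morph sequence of maps
#'
#' @param labels an `rm_labels` object.
#' @param n_maps number of maps, equally spaced in morph index over `[0, 1]`.
#' @return an object of class `rm_morph`: list with `n_maps`, `index_grid`
#'   and an `n_neurons x n_maps` matrix `coords` of angles.
#' @export
morph_sequence <- function(labels, n_maps) {
  stopifnot(inherits(labels, "rm_labels"), n_maps >= 2)
  idx <- seq(0, 1, length.out = n_maps)
  coords <- vapply(idx, function(t) morph_coordinates(labels, t),
                   numeric(nrow(labels)))
  structure(list(n_maps = n_maps, index_grid = idx, coords = coords,
                 labels = labels),
            class = "rm_morph")
}

#' Serialize / read a map realization
#'
#' Writes the per-neuron angles as CSV together with a JSON sidecar holding
#' the generation metadata (n_neurons, d, seed, convention version).
#'
#' @param labels an `rm_labels` object.
#' @param path CSV file path; the sidecar is written at `<path>.json`.
#' @param seed the seed used to create `labels` (stored as metadata only).
#' @export
write_maps <- function(labels, path, seed = NA) {
  stopifnot(inherits(labels, "rm_labels"))
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  meta <- list(n_neurons = nrow(labels), d = attr(labels, "d"),
               seed = seed, convention = "ringmorph-1")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_maps
#' @export
read_maps <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  neuron_labels(df$theta_mid, df$phi, meta$d)
}

# RNG bookkeeping: one top-level seed is split deterministically into
# per-purpose streams so map sampling, noise and initial conditions do not
# interact.
rng_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

rng_restore <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Derive a per-purpose sub-seed from a master seed
#'
#' @param seed master seed (integer).
#' @param purpose character label of the stream ("maps", "noise", "init", ...).
#' @return an integer seed, below 2^31, deterministic in both arguments.
#' @export
split_seed <- function(seed, purpose) {
  stopifnot(length(seed) == 1L)
  cp <- as.numeric(utf8ToInt(purpose))
  h <- sum(cp * seq_along(cp)) * 2654435
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}
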
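#' Circular-geometry helpers
#'
#' All angles in ringmorph are stored in radians in `[0, 2*pi)`. A single
#' canonical wrapping helper is used throughout so that branch-cut behaviour
#' is consistent across the package.
#'
#' @param theta numeric vector of angles (radians, any real value).
#' @return `wrap_angle()` returns angles wrapped to `[0, 2*pi)`.
#' @examples
#' wrap_angle(c(-pi / 2, 7 * pi))
#' circ_dist(0.1, 2 * pi - 0.1)
#' @export
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  # guard against 2*pi slipping through on negative inputs very close to 0
  out[out >= 2 * pi] <- 0
  out
}

#' @rdname wrap_angle
#' @description `wrap_signed()` wraps an angular difference to `(-pi, pi]`.
#' The branch cut sits exactly at `pi`: a difference of exactly `pi` maps to
#' `+pi`, i.e. ties are broken toward the counter-clockwise arc.
#' @export
wrap_signed <- function(theta) {
  out <- (-theta) %% (2 * pi)   # in [0, 2*pi); exact pi stays pi
  -(out - 2 * pi * (out >= pi))
}

#' @rdname wrap_angle
#' @param a,b numeric vectors of angles (radians).
#' @description `circ_dist()` is the unsigned circular distance, the minimum
#' over the two arcs (in `[0, pi]`); `circ_dist_signed()` is the oriented
#' shortest-arc difference `b - a` in `(-pi, pi]` (positive = CCW).
#' @export
circ_dist <- function(a, b) {
  abs(wrap_signed(b - a))
}

#' @rdname wrap_angle
#' @export
circ_dist_signed <- function(a, b) {
  wrap_signed(b - a)
}

#' Circular correlation coefficient
#'
#' Fisher-Lee circular correlation between two samples of angles; used to
#' quantify decorrelation of a map pair as the map-distance parameter grows.
#'
#' @param a,b numeric vectors of angles (radians), same length.
#' @return a value in `[-1, 1]`.
#' @export
circ_corr <- function(a, b) {
  stopifnot(length(a) == length(b))
  da <- sin(a - circ_mean(a))
  db <- sin(b - circ_mean(b))
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

#' @rdname circ_corr
#' @param theta numeric vector of angles.
#' @export
circ_mean <- function(theta) {
  wrap_angle(Arg(sum(exp(1i * theta))))
}
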
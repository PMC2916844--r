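# Stimulation protocols: tuning curves, dynamical pattern separation,
# the delayed shortest-path task, and slow-morph remapping.

#' Piecewise stimulus schedule
#'
#' A protocol is an ordered list of segments, each with a duration and a
#' tuned-input specification (`eps`, `map`, `location`); `eps = 0` gives an
#' unstimulated (delay / pre-stimulus) segment. Segment `location` values
#' may be functions of the time elapsed within the segment.
#'
#' @param ... segments created with [protocol_segment()].
#' @return an object of class `rm_protocol`.
#' @export
stim_protocol <- function(...) {
  segs <- list(...)
  stopifnot(length(segs) > 0)
  durs <- vapply(segs, function(s) s$duration, numeric(1))
  if (any(durs < 0)) stop("segment durations must be >= 0")
  structure(list(segments = segs, ends = cumsum(durs)),
            class = "rm_protocol")
}

#' @rdname stim_protocol
#' @param duration segment duration (>= 0).
#' @inheritParams tuned_input
#' @export
protocol_segment <- function(duration, eps = 0, map = "A", location = 0) {
  list(duration = duration, eps = eps, map = map, location = location)
}

protocol_input <- function(protocol, t) {
  i <- findInterval(t, protocol$ends, left.open = TRUE) + 1
  if (i > length(protocol$segments)) i <- length(protocol$segments)
  seg <- protocol$segments[[i]]
  t_local <- t - if (i == 1) 0 else protocol$ends[i - 1]
  loc <- if (is.function(seg$location)) seg$location(t_local) else seg$location
  tuned_input(eps = seg$eps, map = seg$map, location = loc)
}

#' @rdname stim_protocol
#' @param protocol an `rm_protocol`.
#' @export
protocol_duration <- function(protocol) {
  protocol$ends[length(protocol$ends)]
}

# random initial state on the attractor: the regime's fixed-point shape
# with a random bump angle and (if the regime allows) random offset
random_attractor_state <- function(fp, params, seed, purpose = "init") {
  old <- rng_save(); on.exit(rng_restore(old))
  set.seed(split_seed(seed, purpose))
  h <- admissible_xphi(fp, params)
  op <- fp
  op$psi0 <- stats::runif(1, 0, 2 * pi)
  op$x_phi <- if (h > 0) stats::runif(1, -h, h) else 0
  op
}

#' Admissible half-range of the bump offset
#'
#' The bump can sit at offset `x_phi` without touching the boundary of the
#' distance coordinate as long as `|x_phi| <= pi/2 - size/d` (zero in the
#' single/double-ring regimes, positive in the cylinder regime).
#' @param op an [order_params()] (its `size` is used).
#' @param params a [model_params()].
#' @export
admissible_xphi <- function(op, params) {
  if (params$d <= 0) return(0)
  max(0, pi / 2 - op$size / params$d)
}

#' Estimate tuning curves
#'
#' Presents a static tuned input at each of a grid of locations on each
#' stimulated map, integrates the reduced dynamics to steady state from
#' random initial conditions on the attractor, and reads out the per-neuron
#' responses from the resulting activity profile. In the single-ring regime
#' every neuron prefers the circular midpoint of its two assigned angles in
#' both maps; in the double-ring regime it has one tuning curve per map
#' (coinciding with the assigned angles only at map distance 1); in the
#' cylinder regime the response to a single presentation also depends on
#' the random initial bump offset, so single presentations are unreliable
#' and only the presentation-averaged curve is well defined.
#'
#' @param params a [model_params()] object (`eps` used if > 0, else 0.05).
#' @param labels an `rm_labels` object giving the probed neurons.
#' @param regime optional expected regime label; a mismatch with
#'   [classify_regime()] is an error.
#' @param maps which maps to stimulate (subset of `"A"`, `"B"`).
#' @param n_locations number of input locations (regular grid).
#' @param n_presentations presentations per location (random initial
#'   conditions).
#' @param t_settle settling time per presentation; the default scales
#'   inversely with the tuned fraction, since the bump rotates toward the
#'   input location along a marginal direction at a speed proportional to
#'   `eps`.
#' @param seed integer seed.
#' @return an `rm_tuning` object: `responses` array (neuron x location x
#'   map) of presentation-averaged responses, `response_sd` (same shape,
#'   across presentations), `locations`, `preferred` (neuron x map matrix,
#'   NA when silent), `silent` (neuron x map logical).
#' @export
estimate_tuning_curves <- function(params, labels, regime = NULL,
                                   maps = c("A", "B"), n_locations = 12,
                                   n_presentations = 5,
                                   t_settle = NULL, seed = 1) {
  p <- params
  reg <- classify_regime(p)
  if (!is.null(regime) && reg$label != regime)
    stop(sprintf("parameters are in the %s regime, not %s", reg$label, regime))
  if (is.null(reg$op)) stop("tuning curves need a localized regime")
  eps <- if (p$eps > 0) p$eps else 0.1
  if (is.null(t_settle)) t_settle <- (40 + 30 / eps) * p$tau
  fp <- reg$op
  locs <- seq(0, 2 * pi, length.out = n_locations + 1)[-(n_locations + 1)]
  N <- nrow(labels)
  resp <- array(0, c(N, n_locations, length(maps)),
                dimnames = list(NULL, NULL, maps))
  resp2 <- resp
  kseed <- 0
  for (mi in seq_along(maps)) for (li in seq_along(locs)) {
    acc <- matrix(0, N, n_presentations)
    for (k in seq_len(n_presentations)) {
      kseed <- kseed + 1
      op0 <- random_attractor_state(fp, p, split_seed(seed, paste0("tc", kseed)))
      inp <- tuned_input(eps = eps, map = maps[mi], location = locs[li])
      tr <- integrate_mf(op0, p, inp, t_end = t_settle,
                         dt_sample = t_settle / 4)
      y <- attr(tr, "moments")[nrow(tr), ]
      acc[, k] <- rates_at_labels(y, p, labels, inp, t_settle)
    }
    resp[, li, mi] <- rowMeans(acc)
    resp2[, li, mi] <- apply(acc, 1, stats::sd)
  }
  pop_peak <- max(resp)
  preferred <- matrix(NA_real_, N, length(maps),
                      dimnames = list(NULL, maps))
  silent <- matrix(FALSE, N, length(maps), dimnames = list(NULL, maps))
  for (mi in seq_along(maps)) for (i in seq_len(N)) {
    yv <- resp[i, , mi]
    if (max(yv) < 0.01 * pop_peak) { silent[i, mi] <- TRUE; next }
    preferred[i, mi] <- circular_argmax(locs, yv)
  }
  structure(list(responses = resp, response_sd = resp2, locations = locs,
                 preferred = preferred, silent = silent, labels = labels,
                 regime = reg$label),
            class = "rm_tuning")
}

# argmax over a circular grid with quadratic interpolation; ties resolved
# by the circular mean of the argmax set
circular_argmax <- function(locs, y) {
  n <- length(y)
  imax <- which(y > max(y) - 1e-12)
  if (length(imax) > 1) return(circ_mean(locs[imax]))
  i <- imax
  ym <- y[(i - 2) %% n + 1]; y0 <- y[i]; yp <- y[i %% n + 1]
  denom <- ym - 2 * y0 + yp
  off <- if (abs(denom) < 1e-14) 0 else 0.5 * (ym - yp) / denom
  dloc <- locs[2] - locs[1]
  wrap_angle(locs[i] + off * dloc)
}

#' Dynamical pattern separation under a moving input
#'
#' Drives the network (in the cylinder regime) with a tuned input whose
#' location moves at constant angular velocity on one map. The bump slides
#' to one side of the distance coordinate, determined jointly by the
#' stimulated map and the sign of the velocity, so the set of responsive
#' neurons changes almost completely when the other map is stimulated --
#' and is restored when the velocity is also reversed.
#'
#' @param params cylinder-regime [model_params()] (checked).
#' @param labels `rm_labels` of the probed neurons.
#' @param velocity signed angular speed of the input (rad per time unit).
#' @param map_select stimulated map (`"A"` or `"B"` or morph index).
#' @param t_end run duration (several input revolutions).
#' @param seed integer seed (initial state, and noise if `sigma_noise > 0`).
#' @param eps tuned fraction (default: `params$eps`, or 0.15 if unset).
#' @return an `rm_separation` object: `active` (logical per neuron),
#'   `response` (mean response over the final input revolution), `trace`
#'   (order-parameter trajectory), `x_phi_end`.
#' @export
dynamical_pattern_separation <- function(params, labels, velocity,
                                         map_select = "A", t_end = NULL,
                                         seed = 1, eps = NULL) {
  p <- params
  if (abs(velocity) <= 0) stop("`velocity` must be nonzero")
  reg <- classify_regime(p)
  if (reg$label != "cylinder")
    stop("dynamical pattern separation requires cylinder-regime parameters")
  if (is.null(eps)) eps <- if (p$eps > 0) p$eps else 0.15
  period <- 2 * pi / abs(velocity)
  if (is.null(t_end)) t_end <- 3 * period
  op0 <- random_attractor_state(reg$op, p, seed)
  inp <- tuned_input(eps = eps, map = map_select,
                     location = function(t) velocity * t)
  tr <- integrate_mf(op0, p, inp, t_end = t_end, seed = seed,
                     dt_sample = p$tau)
  # mean response over the last full input revolution
  sel <- tr$time >= t_end - period
  mom <- attr(tr, "moments")[sel, , drop = FALSE]
  tsel <- tr$time[sel]
  resp <- rowMeans(vapply(seq_along(tsel), function(k)
    rates_at_labels(mom[k, ], p, labels, inp, tsel[k]),
    numeric(nrow(labels))))
  active <- resp > 0.01 * max(resp)
  structure(list(active = active, response = resp, trace = tr,
                 x_phi_end = tr$x_phi[nrow(tr)], map = map_select,
                 velocity = velocity),
            class = "rm_separation")
}

#' @rdname dynamical_pattern_separation
#' @param a,b logical activity masks (equal length).
#' @return `subset_overlap()` returns the Jaccard overlap of two active
#'   subsets.
#' @export
subset_overlap <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Delayed shortest-path discrimination task
#'
#' Chained trials with no inter-trial reset: each trial presents a tuned
#' input at angle `xi1` (stimulus 1), removes it for a delay, then presents
#' `xi2` (stimulus 2), all on the same map. While the bump travels from
#' `xi1` to `xi2` along the shortest arc, its offset along the distance
#' coordinate moves to a sign determined by the direction of travel (the
#' memory effect), so the sign of `x_phi` at the end of stimulus 2 reads
#' out whether the shortest path was CW or CCW. With input on map A, CCW
#' travel drives `x_phi` positive (see the package vignette for the sign
#' convention).
#'
#' @param params cylinder-regime [model_params()].
#' @param n_trials number of chained trials (>= 1).
#' @param durations named or positional numeric vector
#'   `(stim1, delay, stim2)`.
#' @param eps tuned fraction during stimuli (default `params$eps` or 0.15).
#' @param map stimulated map for all stimuli.
#' @param undecided_frac `|x_phi|` below this fraction of its admissible
#'   half-range reads out as "undecided".
#' @param seed integer seed (stimulus angles and initial state).
#' @return an `rm_task` object: `trials` data frame (`xi1, xi2, oriented,
#'   x_phi_end, readout, correct`) and `accuracy` summaries (overall and
#'   restricted to `|oriented|` in `[pi/8, 7*pi/8]`).
#' @export
shortest_path_task <- function(params, n_trials = 50,
                               durations = c(stim1 = 800, delay = 800,
                                             stim2 = 800),
                               eps = NULL, map = "A",
                               undecided_frac = 0.05, seed = 1) {
  p <- params
  stopifnot(n_trials >= 1, length(durations) == 3, all(durations >= 0))
  reg <- classify_regime(p)
  if (reg$label != "cylinder")
    stop("the shortest-path task requires cylinder-regime parameters")
  if (is.null(eps)) eps <- if (p$eps > 0) p$eps else 0.15
  fp <- reg$op
  h <- admissible_xphi(fp, p)
  old <- rng_save(); on.exit(rng_restore(old))
  set.seed(split_seed(seed, "task"))
  xi <- matrix(stats::runif(2 * n_trials, 0, 2 * pi), ncol = 2)
  op <- random_attractor_state(fp, p, seed, "task-init")
  # brief unstimulated pre-period, then the chained trials
  tr0 <- integrate_mf(op, p, NULL, t_end = 20 * p$tau)
  y_cur <- attr(tr0, "moments")[nrow(tr0), ]
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    prot <- stim_protocol(
      protocol_segment(durations[1], eps = eps, map = map, location = xi[k, 1]),
      protocol_segment(durations[2], eps = 0),
      protocol_segment(durations[3], eps = eps, map = map, location = xi[k, 2]))
    op_cur <- moments_to_op(y_cur, p)
    tr <- integrate_mf(op_cur, p, prot, t_end = protocol_duration(prot),
                       dt_sample = sum(durations) / 8)
    y_cur <- attr(tr, "moments")[nrow(tr), ]
    xe <- tr$x_phi[nrow(tr)]
    oriented <- circ_dist_signed(xi[k, 1], xi[k, 2])  # xi2 - xi1, CCW > 0
    readout <- if (abs(xe) < undecided_frac * h) "undecided"
               else if (xe > 0) "CCW" else "CW"
    correct <- (readout == "CCW" && oriented > 0) ||
               (readout == "CW" && oriented < 0)
    rows[[k]] <- data.frame(trial = k, xi1 = xi[k, 1], xi2 = xi[k, 2],
                            oriented = oriented, x_phi_end = xe,
                            readout = readout, correct = correct)
  }
  trials <- do.call(rbind, rows)
  mid <- abs(trials$oriented) >= pi / 8 & abs(trials$oriented) <= 7 * pi / 8
  structure(list(trials = trials,
                 accuracy = mean(trials$correct),
                 accuracy_mid = mean(trials$correct[mid]),
                 n_mid = sum(mid), params = p),
            class = "rm_task")
}

#' Slow-morph remapping protocol
#'
#' Morphs the stimulated environment linearly from map A to map B over a
#' duration `T` while the input location sweeps the circle, and compares
#' the evolving network activity with reference runs driven by the same
#' input trajectory in the fixed environments. In the double-ring regime
#' the map-preference readout switches sharply near mid-morph; in the
#' cylinder regime the bump-offset switch happens later, because the bump
#' has to travel across the distance coordinate.
#'
#' @param params a [model_params()] object.
#' @param mode `"two_maps"` (use `params$d`), `"morph_equiv"` (two maps at
#'   the morph-equivalent distance [MORPH_EQUIV_D]) or `"full_morph"`
#'   (finite network storing `n_morph_maps` maps along the sequence).
#' @param eps tuned fraction.
#' @param T_morph morph duration.
#' @param n_laps number of full circles of the input location over the
#'   morph.
#' @param labels optional `rm_labels` used for the correlation readout
#'   (generated from `seed` when NULL).
#' @param n_morph_maps stored maps in `"full_morph"` mode.
#' @param N network size in `"full_morph"` mode.
#' @param seed integer seed.
#' @return an `rm_morphrun`: `trace` (order parameters over time), `corr`
#'   (data frame `time, corr_A, corr_B`), `transition` (list with
#'   `time_mu`, `time_x_phi`, `time_corr` estimates), and `mode`.
#' @export
slow_morph_protocol <- function(params, mode = c("two_maps", "morph_equiv",
                                                 "full_morph"),
                                eps = 0.1, T_morph = 20000, n_laps = 1,
                                labels = NULL, n_morph_maps = 25, N = 400,
                                seed = 1) {
  mode <- match.arg(mode)
  p <- params
  if (mode == "morph_equiv") p$d <- MORPH_EQUIV_D
  if (mode == "full_morph") p$d <- 1  # morphing between uncorrelated refs
  if (is.null(labels))
    labels <- sample_correlated_maps(if (mode == "full_morph") N else 400,
                                     p$d, seed = split_seed(seed, "maps"))
  loc <- function(t) 2 * pi * n_laps * t / T_morph
  morph_idx <- function(t) min(max(t / T_morph, 0), 1)
  run_input <- function(map) {
    if (identical(map, "morph"))
      tuned_input(eps = eps, map = morph_idx, location = loc)
    else
      tuned_input(eps = eps, map = map, location = loc)
  }
  if (mode == "full_morph") {
    seq_maps <- morph_sequence(labels, n_morph_maps)
    coup <- build_coupling(seq_maps, p, mode = "implicit")
    runs <- lapply(list("morph", "A", "B"), function(mp) {
      simulate_network(NULL, coup, p, run_input(mp), t_end = T_morph,
                       seed = seed, dt_sample = T_morph / 200)
    })
    acts <- lapply(runs, function(r) r$rates)
    times <- runs[[1]]$times
    trace <- data.frame(t(vapply(seq_along(times), function(k)
      as_vector_op(estimate_order_params(acts[[1]][k, ], labels, p)),
      numeric(5))))
    names(trace) <- c("amp", "size", "mu", "psi0", "x_phi")
    trace <- cbind(time = times, trace)
  } else {
    reg <- classify_regime(p)
    if (is.null(reg$op)) stop("slow morph needs a localized regime")
    op0 <- random_attractor_state(reg$op, p, seed)
    # start from the state reached under environment-A stimulation with
    # the morph's own input trajectory continued seamlessly backwards in
    # time (same location and velocity at the junction): in the cylinder
    # regime this parks the bump on the A-side of the distance coordinate
    # without a velocity discontinuity at morph onset
    T_pre <- 1200 * p$tau
    v_slow <- 2 * pi * n_laps / T_morph
    pre <- integrate_mf(op0, p,
                        tuned_input(eps = eps, map = "A",
                                    location = function(t)
                                      v_slow * (t - T_pre)),
                        t_end = T_pre)
    op0 <- moments_to_op(attr(pre, "moments")[nrow(pre), ], p)
    if (p$d == 1 && abs(op0$mu) < 1e-6) op0$mu <- 0.1  # nudge off the ridge
    dt_s <- T_morph / 200
    runs <- lapply(list("morph", "A", "B"), function(mp) {
      integrate_mf(op0, p, run_input(mp), t_end = T_morph, seed = seed,
                   dt_sample = dt_s)
    })
    times <- runs[[1]]$time
    acts <- lapply(seq_along(runs), function(j) {
      mom <- attr(runs[[j]], "moments")
      mp <- list("morph", "A", "B")[[j]]
      t(vapply(seq_along(times), function(k)
        rates_at_labels(mom[k, ], p, labels,
                        run_input(mp), times[k]),
        numeric(nrow(labels))))
    })
    trace <- runs[[1]]
  }
  corr <- activity_correlation_timecourse(acts[[1]], acts[[2]], acts[[3]],
                                          times = times)
  structure(list(trace = trace, corr = corr, mode = mode, params = p,
                 labels = labels,
                 transition = list(
                   time_mu = transition_time(trace$time, trace$mu),
                   time_x_phi = transition_time(trace$time, trace$x_phi),
                   time_corr = corr_crossing_time(corr))),
            class = "rm_morphrun")
}

#' Instantaneous activity correlation with reference runs
#'
#' Pearson correlation, across neurons (or grid nodes), between the
#' activity during a morph run and each of two reference runs, at every
#' sample time. Frames with zero variance are flagged as `NA`.
#'
#' @param run,refA,refB activity matrices (time x units) on aligned grids.
#' @param times optional time stamps for the output.
#' @return data frame with `time`, `corr_A`, `corr_B` in `[-1, 1]` or `NA`.
#' @export
activity_correlation_timecourse <- function(run, refA, refB, times = NULL) {
  stopifnot(all(dim(run) == dim(refA)), all(dim(run) == dim(refB)))
  if (is.null(times)) times <- seq_len(nrow(run))
  safe_cor <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
    stats::cor(x, y)
  }
  data.frame(
    time = times,
    corr_A = vapply(seq_len(nrow(run)), function(k)
      safe_cor(run[k, ], refA[k, ]), numeric(1)),
    corr_B = vapply(seq_len(nrow(run)), function(k)
      safe_cor(run[k, ], refB[k, ]), numeric(1)))
}

# time at which a readout trace switches between its initial and final
# plateaus: last crossing of the midpoint level
transition_time <- function(time, y) {
  n <- length(y)
  y0 <- stats::median(y[seq_len(max(3, n %/% 20))])
  y1 <- stats::median(y[(n - max(3, n %/% 20)):n])
  if (abs(y1 - y0) < 1e-9) return(NA_real_)
  z <- (y - (y0 + y1) / 2) * sign(y1 - y0)
  ix <- which(z[-1] >= 0 & z[-n] < 0)
  if (length(ix) == 0) return(NA_real_)
  time[ix[length(ix)] + 1]
}

corr_crossing_time <- function(corr) {
  dz <- corr$corr_B - corr$corr_A
  ok <- which(!is.na(dz))
  if (length(ok) < 2) return(NA_real_)
  ix <- ok[which(dz[ok][-1] >= 0 & dz[ok][-length(ok)] < 0)]
  if (length(ix) == 0) return(NA_real_)
  corr$time[ix[length(ix)] + 1]
}
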
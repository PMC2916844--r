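# Finite-N rate-network simulator.
#
# The coupling between neurons i and j is the sum over stored maps of
# cosine kernels minus a uniform inhibition, scaled by 1/N so that the
# mean-field limit is approached as N grows:
#   J_ij = (1/N) * ( w * sum_k cos(theta_i^k - theta_j^k) - J_inh ),
# with w = J_mod for two stored maps and w = 2*J_mod/K for K morph maps
# (so the total map-specific weight at coincident labels is always
# 2*J_mod). Because the kernel contains only first circular harmonics, the
# recurrent input can be computed exactly through the per-map population
# harmonics in O(N K) per evaluation ("implicit" mode); the dense N x N
# matrix route is retained as the brute-force reference.

#' Build the coupling for a finite network
#'
#' @param labels an `rm_labels` object (two stored maps) or an `rm_morph`
#'   sequence (K stored morph maps).
#' @param params a [model_params()] object.
#' @param mode `"auto"` (implicit above 2000 neurons), `"dense"` or
#'   `"implicit"`. Both modes represent the same operator; implicit mode is
#'   exact for this coupling family, not an approximation.
#' @return an `rm_coupling` object.
#' @export
build_coupling <- function(labels, params,
                           mode = c("auto", "dense", "implicit")) {
  mode <- match.arg(mode)
  if (inherits(labels, "rm_morph")) {
    coords <- labels$coords
    w <- 2 * params$J_mod / ncol(coords)
    base_labels <- labels$labels
  } else if (inherits(labels, "rm_labels")) {
    coords <- cbind(labels$theta_A, labels$theta_B)
    w <- params$J_mod
    base_labels <- labels
  } else stop("`labels` must be an rm_labels or rm_morph object")
  N <- nrow(coords)
  if (mode == "auto") mode <- if (N > 2000) "implicit" else "dense"
  C <- cos(coords); S <- sin(coords)
  out <- list(N = N, w = w, J_inh = params$J_inh, C = C, S = S,
              labels = base_labels,
              meta = list(N = N, n_maps = ncol(coords), d = attr(base_labels, "d"),
                          J_mod = params$J_mod, J_inh = params$J_inh))
  if (mode == "dense") {
    out$weights <- (w * (tcrossprod(C) + tcrossprod(S)) - params$J_inh) / N
    class(out) <- c("rm_coupling_dense", "rm_coupling")
  } else {
    class(out) <- c("rm_coupling_implicit", "rm_coupling")
  }
  out
}

recurrent_input <- function(coupling, rates) {
  UseMethod("recurrent_input")
}

#' @export
recurrent_input.rm_coupling_dense <- function(coupling, rates) {
  as.vector(coupling$weights %*% rates)
}

#' @export
recurrent_input.rm_coupling_implicit <- function(coupling, rates) {
  N <- coupling$N
  hc <- crossprod(coupling$C, rates) / N   # per-map cosine harmonics
  hs <- crossprod(coupling$S, rates) / N
  coupling$w * (as.vector(coupling$C %*% hc) + as.vector(coupling$S %*% hs)) -
    coupling$J_inh * mean(rates)
}

#' Simulate the finite rate network
#'
#' Deterministic mode (`sigma_noise = 0`) integrates the threshold-linear
#' rate equations with the same adaptive RK4(5) scheme as the mean-field
#' dynamics. Noisy mode integrates the current-based formulation with
#' Euler-Maruyama at fixed step `tau/100`, adding independent white noise
#' to each neuron's input current.
#'
#' @param state0 numeric vector of initial rates (or currents in noisy
#'   mode), length N; or `NULL` for a small random state.
#' @param coupling an `rm_coupling` from [build_coupling()].
#' @param params a [model_params()] object.
#' @param input a [tuned_input()] / [stim_protocol()] / function, or `NULL`.
#' @param t_end end time.
#' @param seed integer seed (noise and, when `state0` is NULL, the initial
#'   state).
#' @param dt_sample sampling interval for the returned trajectory.
#' @return an `rm_netrun`: list with `times`, `rates` (time x N matrix of
#'   firing rates) and `labels`.
#' @export
simulate_network <- function(state0 = NULL, coupling, params, input = NULL,
                             t_end, seed = NULL,
                             dt_sample = params$tau / 2) {
  p <- params
  N <- coupling$N
  input <- as_input_fn(input)
  labels <- coupling$labels
  if (is.null(state0)) {
    old <- rng_save(); on.exit(rng_restore(old), add = TRUE)
    set.seed(split_seed(if (is.null(seed)) 0 else seed, "init"))
    state0 <- stats::runif(N, 0, p$I0)
  }
  stopifnot(length(state0) == N)
  times <- seq(0, t_end, by = dt_sample)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  ext <- function(t) {
    inp <- resolve_input(input(t), t, p)
    if (inp$eps > 0) {
      theta_M <- wrap_angle(labels$theta_mid + inp$a * labels$phi)
      p$I0 * (1 + inp$eps * cos(theta_M - inp$xi))
    } else rep(p$I0, N)
  }
  if (p$sigma_noise == 0) {
    f <- function(t, m) (-m + pmax(recurrent_input(coupling, m) + ext(t), 0)) / p$tau
    monitor <- function(t, m) {
      if (any(!is.finite(m)) || max(m) > 1e8 * p$I0)
        list(type = "divergence", time = t) else NULL
    }
    traj <- rk45_integrate(f, state0, times, atol = 1e-8, rtol = 1e-6,
                           monitor = monitor)
    rates <- traj
  } else {
    old <- rng_save(); on.exit(rng_restore(old), add = TRUE)
    set.seed(split_seed(if (is.null(seed)) 0 else seed, "noise"))
    dt <- p$tau / 100
    sq <- p$sigma_noise * sqrt(dt / p$tau)
    u <- state0
    rates <- matrix(NA_real_, length(times), N)
    rates[1, ] <- pmax(u, 0)
    t <- times[1]
    for (i in 2:length(times)) {
      while (t < times[i] - dt / 2) {
        r <- pmax(u, 0)
        u <- u + (dt / p$tau) *
          (-u + recurrent_input(coupling, r) + ext(t)) +
          sq * stats::rnorm(N)
        t <- t + dt
      }
      rates[i, ] <- pmax(u, 0)
    }
    attr(rates, "times") <- times
  }
  structure(list(times = attr(rates, "times"), rates = rates,
                 labels = labels, event = attr(rates, "event"),
                 params = p),
            class = "rm_netrun")
}

#' Estimate order parameters from network activity
#'
#' Computes the mean activity and the first circular harmonics of the
#' activity in the two map coordinates, then inverts the steady-profile
#' moment relations for the five order parameters. The bump shape
#' `(size)` and amplitude are obtained from the mean/modulation ratio,
#' which depends only on the shape, so the estimator recovers any profile
#' of the steady-state family, not only self-consistent fixed points.
#'
#' @param activity numeric vector of firing rates, length N.
#' @param labels an `rm_labels` object.
#' @param params a [model_params()] object (for `d`, `I0` normalisation).
#' @return an [order_params()] estimate; attribute `undefined` flags
#'   angle estimates that are meaningless (zero activity or zero
#'   modulation).
#' @export
estimate_order_params <- function(activity, labels, params) {
  stopifnot(length(activity) == nrow(labels), nrow(labels) >= 10)
  p <- params
  m0 <- mean(activity)
  if (m0 <= 0) {
    op <- order_params(0, -1)
    attr(op, "undefined") <- c("psi0", "x_phi", "mu", "size")
    return(op)
  }
  zA <- mean(activity * exp(1i * labels$theta_A))
  zB <- mean(activity * exp(1i * labels$theta_B))
  RA <- Mod(zA); RB <- Mod(zB); R <- RA + RB
  # modulation below the sampling noise floor of the harmonic estimates is
  # indistinguishable from uniform activity and reported as such
  noise_floor <- 4 * sqrt(mean(activity^2) / length(activity))
  if (R < noise_floor) {
    op <- order_params(m0 / p$I0, pi + 1)
    attr(op, "undefined") <- c("psi0", "x_phi", "mu")
    return(op)
  }
  mu_mom <- (RA - RB) / R     # harmonic imbalance of the activity itself
  if (p$d == 0) mu_mom <- 0
  dphi <- wrap_signed(Arg(zA) - Arg(zB))
  psi0 <- wrap_angle(Arg(zB) + dphi / 2)
  x_phi <- if (p$d > 0 && RA > 1e-8 * R && RB > 1e-8 * R)
    dphi / (2 * p$d) else 0
  # Invert the profile's moment map. The profile parameter `mu` shapes the
  # current, so the activity moments of a profile with parameters
  # (size, mu) have mean/modulation ratio M/(CA+CB) and imbalance
  # (CA-CB)/(CA+CB); these equal the measured ratios only at the solution
  # of the 2-D system below (and coincide with `mu` itself at fixed
  # points). Bracket on a grid first: the ratios are undefined (0/0) where
  # the support is empty.
  ratio_m <- m0 / R
  gfun <- function(s, m) {
    si <- shape_integrals(s, m, x_phi, p$d)
    tot <- si$CA + si$CB
    c(si$M / tot - ratio_m, (si$CA - si$CB) / tot - mu_mom)
  }
  mu <- mu_mom
  size <- NA_real_
  for (it in 1:40) {
    f1 <- function(s) gfun(s, mu)[1]
    sgrid <- seq(0.02, pi + 0.9, length.out = 64)
    fv <- suppressWarnings(vapply(sgrid, f1, numeric(1)))
    ok <- which(is.finite(fv))
    if (length(ok) == 0) break
    sgn <- which(fv[ok][-1] >= 0 & fv[ok][-length(ok)] < 0)
    size_new <- if (length(sgn) > 0)
      stats::uniroot(f1, sgrid[c(ok[sgn[1]], ok[sgn[1] + 1])],
                     tol = 1e-10)$root
    else sgrid[ok[which.min(abs(fv[ok]))]]
    # secant update of mu on the imbalance equation at the new size
    g0 <- gfun(size_new, mu)[2]
    if (!is.finite(g0)) break
    h <- 1e-5
    g1 <- gfun(size_new, min(max(mu + h, -1), 1))[2]
    dmu <- if (abs(g1 - g0) > 1e-14) -g0 * h / (g1 - g0) else 0
    mu_new <- min(max(mu + dmu, -1), 1)
    conv <- !is.na(size) && abs(size_new - size) < 1e-9 &&
      abs(mu_new - mu) < 1e-9
    size <- size_new; mu <- mu_new
    if (conv) break
  }
  if (is.na(size)) {
    op <- order_params(m0 / p$I0, pi + 1, mu = mu_mom, psi0 = psi0,
                       x_phi = x_phi)
    attr(op, "undefined") <- "size"
    return(op)
  }
  si <- shape_integrals(size, mu, x_phi, p$d)
  amp <- (m0 / si$M) / p$I0
  op <- order_params(amp = amp, size = size, mu = mu, psi0 = psi0,
                     x_phi = x_phi)
  attr(op, "undefined") <- character(0)
  op
}
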
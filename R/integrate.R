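# Time integration.
#
# Deterministic runs use an adaptive embedded Runge-Kutta 4(5) pair
# (Dormand-Prince) with absolute/relative tolerances 1e-8/1e-6. Noisy runs
# use fixed-step Euler-Maruyama with dt = tau/100, with the noise entering
# the current-based (field) formulation only.

# Dormand-Prince 5(4) tableau
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

# integrate dy/dt = f(t, y) from times[1] to times[length(times)], returning
# the states at all requested times; `monitor(t, y)` may return a non-NULL
# event to stop early.
rk45_integrate <- function(f, y0, times, atol = 1e-8, rtol = 1e-6,
                           h0 = NULL, monitor = NULL) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = n)
  out[1, ] <- y0
  t <- times[1]; y <- y0
  h <- if (is.null(h0)) (times[2] - times[1]) / 10 else h0
  k <- matrix(0, nrow = n, ncol = 7)
  k[, 1] <- f(t, y)
  event <- NULL
  for (i in 2:length(times)) {
    t_target <- times[i]
    while (t < t_target - 1e-12 * max(1, abs(t_target))) {
      h <- min(h, t_target - t)
      if (h < 1e-12 * max(1, abs(t))) {
        e <- simpleError("step-size underflow in adaptive RK integration")
        e$last_state <- y; e$last_time <- t
        stop(e)
      }
      for (s in 2:7) {
        ys <- y + h * as.vector(k[, 1:(s - 1), drop = FALSE] %*% .dp_a[[s - 1]])
        k[, s] <- f(t + .dp_c[s] * h, ys)
      }
      y5 <- y + h * as.vector(k %*% .dp_b5)
      y4 <- y + h * as.vector(k %*% .dp_b4)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (is.na(err) || !is.finite(err)) err <- 2
      if (err <= 1) {
        t <- t + h
        y <- y5
        k[, 1] <- k[, 7]  # FSAL
        if (!is.null(monitor)) {
          event <- monitor(t, y)
          if (!is.null(event)) break
        }
      } else {
        k[, 1] <- f(t, y)
      }
      h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-10))^0.2))
    }
    out[i, ] <- y
    if (!is.null(event)) {
      out <- out[1:i, , drop = FALSE]
      attr(out, "times") <- times[1:i]
      attr(out, "event") <- event
      return(out)
    }
  }
  attr(out, "times") <- times
  out
}

#' Integrate the reduced order-parameter dynamics
#'
#' Deterministic runs (`sigma_noise = 0`) integrate the exactly-closed
#' five-variable moment dynamics with an adaptive RK4(5) scheme. Noisy runs
#' integrate the current field on a (theta, phi) grid with the
#' Euler-Maruyama scheme (fixed step `tau/100`), adding independent white
#' noise to the input current of each grid node, and report the order
#' parameters estimated from the field; the deterministic reduced equations
#' themselves are never driven by noise directly.
#'
#' Divergence of the activity amplitude (amplitude instability) is detected
#' with a ceiling `amp > 1e6` and reported as an event in the result
#' attributes rather than as an error.
#'
#' @param op0 initial [order_params()] state.
#' @param params a [model_params()] object (`sigma_noise` selects the mode).
#' @param input a [tuned_input()] spec, a [stim_protocol()], or `NULL`.
#' @param t_end end time (> 0); the run starts at 0.
#' @param seed integer seed for the noise stream (noisy mode only).
#' @param dt_sample sampling interval of the returned trajectory.
#' @param n_phi quadrature resolution (reduced mode).
#' @param grid grid resolution for the noisy field mode.
#' @return a data frame with columns `time, amp, size, mu, psi0, x_phi`;
#'   attributes `event` (NULL or an amplitude-instability record) and
#'   `moments` (matrix of the raw moment trajectory).
#' @export
integrate_mf <- function(op0, params, input = NULL, t_end, seed = NULL,
                         dt_sample = params$tau / 2, n_phi = 257,
                         grid = list(n_theta = 128, n_phi = 65)) {
  stopifnot(t_end > 0)
  p <- params
  input <- as_input_fn(input)
  y0 <- op_to_moments(op0, p)
  times <- seq(0, t_end, by = dt_sample)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  amp_ceiling <- 1e6
  if (p$sigma_noise == 0) {
    f <- function(t, y) mf_rhs_moments(y, p, input(t), t, n_phi = n_phi)
    monitor <- function(t, y) {
      amp <- p$J_mod * (Mod(complex(real = y[2], imaginary = y[3])) +
                        Mod(complex(real = y[4], imaginary = y[5]))) / p$I0
      if (!is.finite(amp) || amp > amp_ceiling)
        list(type = "amplitude_instability", time = t) else NULL
    }
    traj <- rk45_integrate(f, y0, times, monitor = monitor)
  } else {
    traj <- em_field_integrate(y0, p, input, times, seed = seed, grid = grid)
  }
  times_out <- attr(traj, "times")
  ops <- t(apply(traj, 1, function(y) {
    as_vector_op(tryCatch(moments_to_op(y, p),
                          error = function(e) order_params(0, -1)))
  }))
  out <- data.frame(time = times_out, ops)
  names(out) <- c("time", "amp", "size", "mu", "psi0", "x_phi")
  attr(out, "event") <- attr(traj, "event")
  attr(out, "moments") <- traj
  attr(out, "params") <- p
  out
}

# Euler-Maruyama on the current field over a product grid; the field nodes
# act as a finite quadrature-weighted population, so order-parameter
# fluctuations shrink with grid resolution as they do with network size.
em_field_integrate <- function(y0, params, input_fn, times, seed = NULL,
                               grid = list(n_theta = 128, n_phi = 65)) {
  p <- params
  if (!is.null(seed)) {
    old <- rng_save(); on.exit(rng_restore(old))
    set.seed(split_seed(seed, "noise"))
  }
  nth <- grid$n_theta; nph <- grid$n_phi
  g <- phi_grid(nph)
  theta <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  cth <- cos(theta); sth <- sin(theta)
  eA <- exp(1i * p$d * g$phi); eB <- Conj(eA)
  # initial current field consistent with y0
  inp0 <- resolve_input(input_fn(times[1]), times[1], p)
  W <- input_field_W(y0, p, inp0, g$phi)
  u <- outer(cth, Re(W)) + outer(sth, Im(W)) + (p$I0 - p$J_inh * y0[1])
  dt <- p$tau / 100
  sq <- p$sigma_noise * sqrt(dt / p$tau)
  moments_of <- function(r) {
    m_phi <- colMeans(r)
    zpsi <- complex(real = colMeans(r * cth), imaginary = colMeans(r * sth))
    c(sum(g$w * m_phi),
      Re(sum(g$w * eA * zpsi)), Im(sum(g$w * eA * zpsi)),
      Re(sum(g$w * eB * zpsi)), Im(sum(g$w * eB * zpsi)))
  }
  out <- matrix(NA_real_, nrow = length(times), ncol = 5)
  out[1, ] <- moments_of(pmax(u, 0))
  t <- times[1]
  for (i in 2:length(times)) {
    while (t < times[i] - dt / 2) {
      r <- pmax(u, 0)
      y <- moments_of(r)
      inp <- resolve_input(input_fn(t), t, p)
      Wt <- input_field_W(y, p, inp, g$phi)
      h_det <- outer(cth, Re(Wt)) + outer(sth, Im(Wt)) +
        (p$I0 - p$J_inh * y[1])
      u <- u + (dt / p$tau) * (h_det - u) +
        sq * matrix(stats::rnorm(nth * nph), nth, nph)
      t <- t + dt
    }
    out[i, ] <- moments_of(pmax(u, 0))
  }
  attr(out, "times") <- times
  out
}

# normalise the various input forms to a function of time returning an
# rm_input (resolve_input is applied downstream)
as_input_fn <- function(input) {
  if (is.null(input)) return(function(t) NULL)
  if (inherits(input, "rm_input")) return(function(t) input)
  if (inherits(input, "rm_protocol")) return(function(t) protocol_input(input, t))
  if (is.function(input)) return(input)
  stop("`input` must be NULL, a tuned_input(), a stim_protocol() or a function")
}
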
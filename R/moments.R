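# Moment-space representation of the reduced dynamics.
#
# The network activity enters its own dynamics only through three
# macroscopic quantities: the mean activity m0 and the first circular
# harmonics zA, zB of the activity with respect to the two map coordinates.
# The rate equation is threshold-linear in a current field that is fully
# determined by (m0, zA, zB) plus the external input, so the dynamics of
# these five real numbers closes exactly. The five named order parameters
# (amp, size, mu, psi0, x_phi) are an invertible reparametrisation of the
# moment vector, given the model parameters.
#
# moment vector layout: y = c(m0, Re(zA), Im(zA), Re(zB), Im(zB))

op_to_moments <- function(op, params) {
  p <- params
  if (p$J_mod <= 0) stop("op/moment conversion requires J_mod > 0")
  if (p$J_inh == 0) stop("op/moment conversion requires J_inh != 0")
  t0 <- size_to_threshold(op$size)
  R <- p$I0 * op$amp / p$J_mod
  RA <- R * (1 + op$mu) / 2
  RB <- R * (1 - op$mu) / 2
  phiA <- op$psi0 + p$d * op$x_phi
  phiB <- op$psi0 - p$d * op$x_phi
  zA <- RA * exp(1i * phiA)
  zB <- RB * exp(1i * phiB)
  m0 <- p$I0 * (op$amp * t0 + 1) / p$J_inh
  c(m0 = m0, ReA = Re(zA), ImA = Im(zA), ReB = Re(zB), ImB = Im(zB))
}

moments_to_op <- function(y, params) {
  p <- params
  zA <- complex(real = y[2], imaginary = y[3])
  zB <- complex(real = y[4], imaginary = y[5])
  RA <- Mod(zA); RB <- Mod(zB)
  R <- RA + RB
  amp <- p$J_mod * R / p$I0
  if (R < .Machine$double.eps) {
    # no spatial modulation: homogeneous-type state
    t0 <- if (y[1] > 0) (p$J_inh * y[1] - p$I0) / (p$I0 * max(amp, 1e-300))
          else Inf
    return(order_params(amp = 0, size = threshold_to_size(sign(t0) * 2),
                        mu = 0, psi0 = 0, x_phi = 0))
  }
  mu <- (RA - RB) / R
  if (p$d == 0) mu <- 0  # convention: degenerate at identical maps
  aA <- Arg(zA); aB <- Arg(zB)
  if (RA < 1e-12 * R) aA <- aB
  if (RB < 1e-12 * R) aB <- aA
  dphi <- wrap_signed(aA - aB)          # = 2 d x_phi along the shortest arc
  psi0 <- wrap_angle(aB + dphi / 2)
  x_phi <- if (p$d > 0 && RA > 1e-12 * R && RB > 1e-12 * R)
    dphi / (2 * p$d) else 0
  t0 <- (p$J_inh * y[1] - p$I0) / (p$I0 * amp)
  order_params(amp = amp, size = threshold_to_size(t0), mu = mu,
               psi0 = psi0, x_phi = x_phi)
}

# closed-form circular moments of a rectified cosine ------------------------
# For a current slice h(x) = rho * cos(x) + b with x uniform on the circle:
#   P0 = <[h]_+>,  P1 = <[h]_+ cos(x)>  (the sine moment vanishes).
# Vectorised over slices.
rectified_cosine_moments <- function(rho, b) {
  n <- length(rho)
  P0 <- numeric(n); P1 <- numeric(n)
  flat <- rho < .Machine$double.eps
  P0[flat] <- pmax(b[flat], 0)
  act <- !flat
  if (any(act)) {
    c0 <- b[act] / rho[act]
    full <- c0 >= 1          # above threshold everywhere
    none <- c0 <= -1         # below threshold everywhere
    part <- !(full | none)
    i <- which(act)
    P0[i[full]] <- b[act][full]
    P1[i[full]] <- rho[act][full] / 2
    if (any(part)) {
      xc <- acos(-c0[part])   # support is |x| < xc
      rr <- rho[act][part]; bb <- b[act][part]
      P0[i[part]] <- (rr * sin(xc) + bb * xc) / pi
      P1[i[part]] <- (rr * (xc / 2 + sin(2 * xc) / 4) + bb * sin(xc)) / pi
    }
  }
  list(P0 = P0, P1 = P1)
}

# trapezoid weights over the distance coordinate, normalised to mean weight
phi_grid <- function(n_phi) {
  phi <- seq(-PHI_HALF_WIDTH, PHI_HALF_WIDTH, length.out = n_phi)
  w <- rep(1, n_phi); w[c(1, n_phi)] <- 0.5
  w <- w / sum(w)
  list(phi = phi, w = w)
}

# external input specification ----------------------------------------------
# The tuned input is eps * I0 * cos(theta_M - xi) on top of the uniform
# baseline I0; theta_M is the neuron's angle on the stimulated map, selected
# by `map`: "A", "B", "mid", or a numeric morph index in [0, 1]
# (A = index 0, B = index 1). `location` and `map` may be functions of time.
map_coefficient <- function(map, d) {
  if (is.character(map)) {
    switch(map,
           A = d, B = -d, mid = 0,
           stop("unknown map selector: ", map))
  } else {
    if (any(map < 0 | map > 1)) stop("morph index must be in [0, 1]")
    (1 - 2 * map) * d
  }
}

#' Tuned-input specification
#'
#' @param eps tuned fraction of the baseline input (0 switches it off).
#' @param map stimulated map: `"A"`, `"B"`, `"mid"`, a morph index in
#'   `[0, 1]`, or a function of time returning any of these.
#' @param location input angle (radians), or a function of time.
#' @return an object of class `rm_input`.
#' @export
tuned_input <- function(eps = 0, map = "A", location = 0) {
  structure(list(eps = eps, map = map, location = location),
            class = "rm_input")
}

resolve_input <- function(input, t, params) {
  if (is.null(input) || (is.numeric(input$eps) && input$eps == 0 &&
                         !is.function(input$eps)))
    return(list(eps = 0, a = 0, xi = 0))
  eps <- if (is.function(input$eps)) input$eps(t) else input$eps
  map <- if (is.function(input$map)) input$map(t) else input$map
  xi <- if (is.function(input$location)) input$location(t) else input$location
  list(eps = eps, a = map_coefficient(map, params$d), xi = xi)
}
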
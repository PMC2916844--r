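# Linear stability analysis.
#
# The homogeneous state admits a closed-form two-mode analysis: a uniform
# (amplitude) perturbation and a spatially modulated (Turing) perturbation
# decouple exactly, giving the two independent stability conditions. For
# localized states the reduced dynamics is linearized numerically around
# the fixed point in moment space; marginal directions from the continuous
# symmetries (bump angle, and the distance-coordinate offset in the
# cylinder regime) are structural and are projected out of the verdict.

#' Stability of the homogeneous (uniform) state
#'
#' Two independent conditions govern stability: the uniform-amplitude mode,
#' with rate `-(1 + J_inh)/tau`, and the dominant spatially modulated
#' (Turing) mode, with rate `(-1 + J_mod (1 + sinc(pi d)) / 2) / tau`. The
#' Turing rate crosses zero exactly on [homogeneous_boundary()].
#'
#' @param params a [model_params()] object.
#' @return an `rm_stability` report: eigenvalues (named), `stable`,
#'   `failing_mode` in `none/amplitude/turing`.
#' @export
homogeneous_stability <- function(params) {
  p <- params
  g <- if (p$d == 0) 1 else sin(pi * p$d) / (pi * p$d)
  lam <- c(amplitude = -(1 + p$J_inh) / p$tau,
           turing = (-1 + p$J_mod * (1 + g) / 2) / p$tau,
           turing_minor = (-1 + p$J_mod * (1 - g) / 2) / p$tau)
  failing <- if (all(lam < 0)) "none"
             else names(lam)[which.max(lam)]
  if (failing == "turing_minor") failing <- "turing"
  structure(list(eigenvalues = lam, stable = all(lam < 0),
                 failing_mode = failing, matrix = diag(lam[1:2])),
            class = "rm_stability")
}

#' @export
print.rm_stability <- function(x, ...) {
  cat("stability:", if (x$stable) "stable" else
    paste0("UNSTABLE (", x$failing_mode, ")"), "\n")
  cat("eigenvalues:", paste(sprintf("%.4g", Re(x$eigenvalues)),
                            collapse = ", "), "\n")
  invisible(x)
}

# 5x5 Jacobian of the moment dynamics by central differences
mf_jacobian_moments <- function(y, params, n_phi = 257, h = 1e-6,
                                method = c("reduced", "grid")) {
  method <- match.arg(method)
  f <- if (method == "reduced")
    function(y) mf_rhs_moments(y, params, n_phi = n_phi)
  else
    function(y) mf_rhs_moments_grid(y, params)
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    e <- numeric(5); e[j] <- h * max(1, abs(y[j]))
    J[, j] <- (f(y + e) - f(y - e)) / (2 * e[j])
  }
  J
}

#' Stability of a localized fixed point
#'
#' Linearizes the five-variable reduced dynamics around a fixed point and
#' reports the eigenvalues. The exactly-marginal directions implied by the
#' continuous symmetries (rotation of the bump angle; translation of the
#' bump along the distance coordinate when its support is interior) are
#' identified by their eigenvector overlap with the symmetry generators and
#' excluded from the stability verdict. For symmetric (`mu = 0`) fixed
#' points the map-preference perturbation decouples; its sign change marks
#' the single-ring/double-ring transition.
#'
#' @param fixed_point an [order_params()] fixed point (residual checked).
#' @param params a [model_params()] object.
#' @param n_phi quadrature resolution.
#' @param tol_resid precondition tolerance on the fixed-point residual.
#' @param tol_marginal rate threshold (in units of `1/tau`) below which an
#'   eigenmode aligned with a symmetry generator is treated as marginal.
#' @return an `rm_stability` report with fields `eigenvalues` (all five),
#'   `marginal` (logical mask), `stable`, `failing_mode` in
#'   `none/amplitude/mu_symmetry_breaking/other`, and the Jacobian.
#' @export
localized_stability <- function(fixed_point, params, n_phi = 257,
                                tol_resid = 1e-7, tol_marginal = 1e-2) {
  p <- params
  y <- op_to_moments(fixed_point, p)
  resid <- max(abs(mf_rhs_moments(y, p, n_phi = n_phi))) * p$tau
  if (resid > tol_resid)
    stop(sprintf("not a fixed point: residual %.3g exceeds %.3g",
                 resid, tol_resid))
  J <- mf_jacobian_moments(y, p, n_phi = n_phi)
  eg <- eigen(J)
  # symmetry generators in moment space
  zA <- complex(real = y[2], imaginary = y[3])
  zB <- complex(real = y[4], imaginary = y[5])
  gens <- list(psi0 = c(0, -Im(zA), Re(zA), -Im(zB), Re(zB)))
  interior <- p$d > 0 &&
    fixed_point$size / p$d + abs(fixed_point$x_phi) < pi / 2 - 1e-9
  if (interior)  # d(phiA)/d(x_phi) = +d, d(phiB)/d(x_phi) = -d
    gens$x_phi <- c(0, -p$d * Im(zA), p$d * Re(zA),
                    p$d * Im(zB), -p$d * Re(zB))
  gen_mat <- do.call(cbind, gens)
  gen_mat <- qr.Q(qr(gen_mat))
  # structural marginality: eigenvector lies in the span of the symmetry
  # generators and the rate is small (the x_phi zero mode carries an
  # O(n_phi^-2) quadrature residue, so the gate cannot be machine-tight)
  marginal <- vapply(seq_along(eg$values), function(i) {
    v <- eg$vectors[, i]
    if (abs(Re(eg$values[i])) > tol_marginal / p$tau) return(FALSE)
    vv <- cbind(Re(v), Im(v))
    pr <- gen_mat %*% crossprod(gen_mat, vv)
    sum(Mod(pr)^2) / sum(Mod(vv)^2) > 0.5
  }, logical(1))
  lead <- Re(eg$values)
  lead[marginal] <- -Inf
  stable <- all(lead < 1e-10)
  failing <- "none"
  if (!stable) {
    # classify the leading unstable mode by its overlap with the
    # order-parameter coordinate directions
    T <- op_jacobian(fixed_point, p)   # d(moments)/d(op), columns named
    v <- Re(eg$vectors[, which.max(lead)])
    coef <- tryCatch(solve(T, v), error = function(e) rep(NA_real_, 5))
    names(coef) <- c("amp", "size", "mu", "psi0", "x_phi")
    top <- names(which.max(abs(coef)))
    failing <- switch(top,
                      mu = "mu_symmetry_breaking",
                      amp = "amplitude", size = "amplitude",
                      "other")
  }
  structure(list(eigenvalues = eg$values, marginal = marginal,
                 stable = stable, failing_mode = failing, jacobian = J,
                 residual = resid),
            class = "rm_stability")
}

# numerical d(moments)/d(op)
op_jacobian <- function(op, params, h = 1e-6) {
  v0 <- as_vector_op(op)
  T <- matrix(0, 5, 5)
  for (j in 1:5) {
    vp <- v0; vm <- v0
    vp[j] <- vp[j] + h; vm[j] <- vm[j] - h
    opp <- order_params(max(vp[1], 0), vp[2], min(max(vp[3], -1), 1), vp[4], vp[5])
    opm <- order_params(max(vm[1], 0), vm[2], min(max(vm[3], -1), 1), vm[4], vm[5])
    T[, j] <- (op_to_moments(opp, params) - op_to_moments(opm, params)) /
      (vp[j] - vm[j])
  }
  T
}
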
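p_sr <- regime_presets("single_ring")

test_that("steady profile is threshold-linear with I0-invariant shape", {
  p <- model_params(d = 0.5, J_mod = 8, J_inh = 10)
  # size <= 0: no activity anywhere
  pr0 <- steady_profile(order_params(2, -0.1), p)
  expect_true(all(pr0$values == 0))
  # maximal size: strictly positive everywhere (all neurons active)
  pr1 <- steady_profile(order_params(2, pi + 0.5), p)
  expect_true(all(pr1$values > 0))
  # doubling I0 doubles values, support unchanged
  op <- order_params(2, 1.1, mu = 0.4, psi0 = 0.7, x_phi = 0.2)
  a <- steady_profile(op, p)
  p2 <- p; p2$I0 <- 2 * p$I0
  b <- steady_profile(op, p2)
  expect_equal(b$values, 2 * a$values, tolerance = 1e-12)
  expect_identical(b$values > 0, a$values > 0)
  expect_true(all(a$values >= 0))
})

test_that("the moment reduction closes: field dynamics matches the 5-ODE", {
  # evolve the full rate field on a grid from an initial condition carrying
  # higher harmonics; its five moments must follow the reduced dynamics to
  # quadrature accuracy (this is the exact-closure property)
  p <- model_params(d = 0.6, J_mod = 6, J_inh = 8, tau = 10)
  nth <- 96; nph <- 65
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  ph <- seq(-pi / 2, pi / 2, length.out = nph)
  wp <- rep(1, nph); wp[c(1, nph)] <- 0.5; wp <- wp / sum(wp)
  set.seed(1)
  m <- outer(th, ph, function(u, v)
    0.3 + 0.2 * cos(u) * cos(0.6 * v) + 0.15 * cos(2 * u) +
      0.1 * sin(3 * u + v))
  m <- pmax(m, 0)
  moments_of <- function(m) {
    mz <- colMeans(m)
    zc <- colMeans(m * cos(th)); zs <- colMeans(m * sin(th))
    zpsi <- complex(real = zc, imaginary = zs)
    eA <- exp(1i * p$d * ph)
    c(sum(wp * mz), Re(sum(wp * eA * zpsi)), Im(sum(wp * eA * zpsi)),
      Re(sum(wp * Conj(eA) * zpsi)), Im(sum(wp * Conj(eA) * zpsi)))
  }
  y <- moments_of(m)
  # field integration (Euler, small steps) vs reduced RK45
  dt <- p$tau / 200
  for (k in 1:400) {
    yk <- moments_of(m)
    W <- ringmorph:::input_field_W(yk, p, list(eps = 0, a = 0, xi = 0), ph)
    h <- outer(cos(th), Re(W)) + outer(sin(th), Im(W)) + (p$I0 - p$J_inh * yk[1])
    m <- m + (dt / p$tau) * (pmax(h, 0) - m)
  }
  y_field <- moments_of(m)
  f <- function(t, y) ringmorph:::mf_rhs_moments(y, p)
  y_red <- ringmorph:::rk45_integrate(f, y, c(0, 400 * dt))[2, ]
  expect_equal(y_field, y_red, tolerance = 2e-3)

  # the drive of a higher harmonic is determined by the five moments:
  # two fields with identical five moments but different higher harmonics
  # receive identical currents
  m1 <- outer(th, ph, function(u, v) 0.5 + 0.2 * cos(u) * cos(0.6 * v))
  m2 <- m1 + outer(0.2 * cos(2 * th), rep(1, nph))
  expect_equal(moments_of(m1), moments_of(m2), tolerance = 1e-12)
  h_of <- function(m) {
    yk <- moments_of(m)
    W <- ringmorph:::input_field_W(yk, p, list(eps = 0, a = 0, xi = 0), ph)
    outer(cos(th), Re(W)) + outer(sin(th), Im(W)) + (p$I0 - p$J_inh * yk[1])
  }
  expect_equal(h_of(m1), h_of(m2), tolerance = 1e-12)
})

test_that("order_param_rhs: gauge invariance, quadrature convergence, fixed point", {
  p <- model_params(d = 0.4, J_mod = 8, J_inh = 10)
  fp <- solve_fixed_point(p)
  # residual at the fixed point
  expect_lt(max(abs(order_param_rhs(fp, p))), 1e-9)
  # with eps = 0, shifting psi0 leaves the first four derivatives unchanged
  op <- order_params(2, 1.0, mu = 0.2, psi0 = 0, x_phi = 0.1)
  r1 <- order_param_rhs(op, p)
  op2 <- op; op2$psi0 <- 2.1
  r2 <- order_param_rhs(op2, p)
  expect_equal(r1[c("amp", "size", "mu", "x_phi")],
               r2[c("amp", "size", "mu", "x_phi")], tolerance = 1e-12)
  # grid-quadrature self-consistency: n vs 2n vs the closed-form path
  g1 <- order_param_rhs(op, p, method = "grid", n_theta = 64, n_phi = 33)
  g2 <- order_param_rhs(op, p, method = "grid", n_theta = 128, n_phi = 65)
  rr <- order_param_rhs(op, p, method = "reduced")
  expect_lt(max(abs(g2 - rr)), max(abs(g1 - rr)))
  expect_equal(g2, rr, tolerance = 5e-3)
})

test_that("shape integrals agree with brute-force 2-D quadrature", {
  for (cs in list(c(1.2, 0, 0.6), c(0.8, 0, 0.3), c(2.0, 0, 0.95))) {
    si <- ringmorph:::shape_integrals(cs[1], cs[2], 0, cs[3])
    br <- brute_shape_moments(cs[1], cs[2], 0, cs[3])
    expect_equal(si$M, br$M, tolerance = 1e-4)
    expect_equal(si$CA + si$CB, br$CAplusCB, tolerance = 1e-4)
  }
})

test_that("integrate_mf holds fixed points, reports divergence, pins the bump", {
  p <- model_params(d = 0.4, J_mod = 8, J_inh = 10)
  fp <- solve_fixed_point(p)
  tr <- integrate_mf(fp, p, NULL, t_end = 100 * p$tau)
  expect_lt(max(abs(as_vector_op(fp) - unlist(tr[nrow(tr), -1]))), 1e-7)
  expect_null(attr(tr, "event"))

  # inhibition below critical: amplitude-instability event, not an error
  pu <- p; pu$J_inh <- attr(fp, "J_inh_critical") * 0.95
  tru <- integrate_mf(fp, pu, NULL, t_end = 4000)
  expect_equal(attr(tru, "event")$type, "amplitude_instability")

  # a static tuned input pinpoints the bump angle (approach along the
  # marginal direction is exponential with rate ~ eps/tau)
  xi <- 2.4
  tr2 <- integrate_mf(fp, p, tuned_input(eps = 0.2, map = "A", location = xi),
                      t_end = 600 * p$tau)
  expect_lt(circ_dist(tr2$psi0[nrow(tr2)], xi), 0.02)
})

test_that("order parameters are I0-invariant and input-rotation equivariant", {
  p <- model_params(d = 0.4, J_mod = 8, J_inh = 10)
  fp <- solve_fixed_point(p)
  p2 <- p; p2$I0 <- 3.7
  fp2 <- solve_fixed_point(p2)
  expect_equal(as_vector_op(fp), as_vector_op(fp2), tolerance = 1e-10)

  # rotating the tuned input and the initial condition together rotates
  # psi0 and leaves everything else exactly unchanged
  run <- function(xi, psi0_init) {
    op0 <- fp; op0$psi0 <- psi0_init
    tr <- integrate_mf(op0, p, tuned_input(eps = 0.1, map = "A",
                                           location = xi),
                       t_end = 150 * p$tau)
    unlist(tr[nrow(tr), -1])
  }
  a <- run(0.5, 0.2); b <- run(0.5 + 1.1, 0.2 + 1.1)
  expect_equal(circ_dist(b[["psi0"]] - a[["psi0"]], 1.1), 0, tolerance = 1e-8)
  expect_equal(a[c("amp", "size", "mu", "x_phi")],
               b[c("amp", "size", "mu", "x_phi")], tolerance = 1e-8)
})

test_that("d = 0 reduces to the classical single-map ring model", {
  for (J in c(3, 6)) {
    p <- model_params(d = 0, J_mod = J, J_inh = 8)
    fp <- solve_fixed_point(p)
    # oracle: 1-map ring with kernel (2 J_mod) cos, brute-force quadrature
    expect_equal(fp$size, ring_oracle_size(2 * J), tolerance = 1e-7)
    expect_equal(fp$mu, 0)
  }
})

test_that("morph coupling kernel: symmetry, coincidence value, equivalence", {
  p <- model_params(d = 1, J_mod = 2, J_inh = 3)
  lab <- sample_correlated_maps(60, 1, seed = 5)
  k2 <- morph_coupling_kernel(p, "two_maps")
  kf <- morph_coupling_kernel(p, "full_morph")
  i <- sample(60); j <- sample(60)
  li <- lab[i, ]; lj <- lab[j, ]
  expect_equal(k2(li, lj), k2(lj, li), tolerance = 1e-12)
  expect_equal(kf(li, lj), kf(lj, li), tolerance = 1e-12)
  # coincident labels: 2 J_mod - J_inh
  expect_equal(k2(lab[1, ], lab[1, ]), 2 * p$J_mod - p$J_inh)
  expect_equal(kf(lab[1, ], lab[1, ]), 2 * p$J_mod - p$J_inh)

  # full-morph closed form equals the K -> infinity limit of the stored sum
  # (trapezoidal quadrature over the morph index as the oracle)
  K <- 2001
  tgrid <- seq(0, 1, length.out = K)
  wt <- rep(1, K); wt[c(1, K)] <- 0.5; wt <- wt / sum(wt)
  num <- sapply(seq_len(20), function(r) {
    di <- lab[i[r], ]; dj <- lab[j[r], ]
    sum(wt * cos((di$theta_mid - dj$theta_mid) +
                   (1 - 2 * tgrid) * (di$phi - dj$phi))) * 2 * p$J_mod -
      p$J_inh
  })
  expect_equal(kf(lab[i[1:20], ], lab[j[1:20], ]), num, tolerance = 1e-6)

  # first-order two-map approximant at the equivalent distance: deviation
  # small and reported
  keq <- morph_coupling_kernel(p, "two_maps", d_pair_equiv = MORPH_EQUIV_D)
  dev <- max(abs(kf(li, lj) - keq(li, lj)))
  expect_lt(dev, 0.5 * p$J_mod)
  # quadratic terms match: cos(d_eq x) - sinc(x) = O(x^4)
  x <- 1e-2
  expect_lt(abs(cos(MORPH_EQUIV_D * x) - sin(x) / x), 1e-9)
})
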
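test_that("tuning curves: single-ring midpoint, double-ring assigned angles", {
  lab <- sample_correlated_maps(25, 0.2, seed = 21)
  tc <- estimate_tuning_curves(regime_presets("single_ring"), lab,
                               regime = "single_ring", n_locations = 10,
                               n_presentations = 2, seed = 3)
  expect_true(all(tc$responses >= 0))
  mid <- wrap_angle(lab$theta_mid)
  # one tuning curve per neuron, identical in both maps, peaked at the
  # circular midpoint of the two assigned angles
  expect_lt(max(circ_dist(tc$preferred[, "A"], mid), na.rm = TRUE), 0.1)
  expect_lt(max(circ_dist(tc$preferred[, "A"], tc$preferred[, "B"]),
                na.rm = TRUE), 0.1)

  labD <- sample_correlated_maps(25, 1, seed = 22)
  tcD <- estimate_tuning_curves(regime_presets("double_ring"), labD,
                                n_locations = 10, n_presentations = 2,
                                seed = 3)
  # uncorrelated maps: preferred angles coincide with the assigned ones
  expect_lt(stats::median(circ_dist(tcD$preferred[, "A"], labD$theta_A),
                          na.rm = TRUE), 0.05)
  expect_lt(stats::median(circ_dist(tcD$preferred[, "B"], labD$theta_B),
                          na.rm = TRUE), 0.05)

  # regime precondition is enforced
  expect_error(
    estimate_tuning_curves(regime_presets("single_ring"), lab,
                           regime = "cylinder"),
    "single_ring")
})

test_that("cylinder responses to a fixed input are unreliable across presentations", {
  p <- regime_presets("cylinder")
  reg <- classify_regime(p)
  fp <- reg$op
  lab <- sample_correlated_maps(120, p$d, seed = 31)
  n_pres <- 14
  resp <- matrix(0, nrow(lab), n_pres)
  for (k in seq_len(n_pres)) {
    op0 <- ringmorph:::random_attractor_state(fp, p, ringmorph::split_seed(40, paste0("u", k)))
    inp <- tuned_input(eps = p$eps, map = "A", location = 1.0)
    tr <- integrate_mf(op0, p, inp, t_end = 120 * p$tau,
                       dt_sample = 60 * p$tau)
    y <- attr(tr, "moments")[nrow(tr), ]
    resp[, k] <- ringmorph:::rates_at_labels(y, p, lab, inp, 0)
  }
  thr <- 0.01 * max(resp)
  frac_resp <- rowMeans(resp > thr)
  # unreliable coding: a sizeable set of neurons responds on some
  # presentations only, and every mid-|phi| neuron whose averaged tuning
  # curve predicts a response at this location is silent on at least one
  # presentation (the random initial bump offset decides)
  expect_gt(sum(frac_resp > 0 & frac_resp < 1), 10)
  midphi <- abs(lab$phi) > 0.3 & abs(lab$phi) < 1.2
  responders <- midphi & frac_resp > 0
  expect_gt(sum(responders), 0)
  expect_true(all(frac_resp[responders] < 1))
})

test_that("dynamical pattern separation and the map/velocity duality", {
  p <- regime_presets("cylinder")
  lab <- sample_correlated_maps(400, p$d, seed = 11)
  v <- 2 * pi / 4000
  sA <- dynamical_pattern_separation(p, lab, v, "A", seed = 5)
  sB <- dynamical_pattern_separation(p, lab, v, "B", seed = 5)
  sBm <- dynamical_pattern_separation(p, lab, -v, "B", seed = 5)
  # swapping the stimulated map flips the bump offset and the active subset
  expect_lt(subset_overlap(sA$active, sB$active), 0.2)
  expect_lt(sA$x_phi_end * sB$x_phi_end, 0)
  # (map A, +v) and (map B, -v) are the same condition
  expect_gt(subset_overlap(sA$active, sBm$active), 0.95)
  # neurons shared between the two maps' subsets sit near phi = 0
  shared <- sA$active & sB$active
  if (any(shared)) expect_lt(max(abs(lab$phi[shared])), 0.5)
  # non-cylinder parameters are rejected
  expect_error(
    dynamical_pattern_separation(regime_presets("single_ring"), lab, v),
    "cylinder")
})

test_that("pattern separation survives input noise across seeds", {
  p <- regime_presets("cylinder"); p$sigma_noise <- 0.1
  lab <- sample_correlated_maps(250, p$d, seed = 13)
  cp <- build_coupling(lab, p, "implicit")
  v <- 2 * pi / 2000
  classify <- function(seed) {
    run <- simulate_network(NULL, cp, p,
                            tuned_input(eps = p$eps, map = "A",
                                        location = function(t) v * t),
                            t_end = 5000, seed = seed,
                            dt_sample = 100)
    sel <- run$times >= 3000
    resp <- colMeans(run$rates[sel, , drop = FALSE])
    resp > 0.01 * max(resp)
  }
  c1 <- classify(1); c2 <- classify(2)
  expect_gt(mean(c1 == c2), 0.95)
})

test_that("shortest-path task: readout, chaining, determinism", {
  p <- regime_presets("cylinder_task")
  tk <- shortest_path_task(p, n_trials = 8, seed = 12)
  expect_equal(nrow(tk$trials), 8)
  expect_true(all(tk$trials$readout %in% c("CW", "CCW", "undecided")))
  # CCW shortest arcs read out positive x_phi (and vice versa) for clear
  # mid-range arcs
  mid <- abs(tk$trials$oriented) > pi / 4 & abs(tk$trials$oriented) < 3 * pi / 4
  expect_true(all(sign(tk$trials$x_phi_end[mid]) ==
                    sign(tk$trials$oriented[mid])))
  # protocol determinism
  tk2 <- shortest_path_task(p, n_trials = 8, seed = 12)
  expect_identical(tk$trials, tk2$trials)

  # degenerate pair xi2 == xi1: no bump travel, so the offset stays in the
  # undecided band (start with the bump already at the stimulus angle --
  # any travel would itself engage the memory effect)
  reg <- classify_regime(p)
  h <- admissible_xphi(reg$op, p)
  op0 <- reg$op; op0$psi0 <- 1
  prot <- stim_protocol(
    protocol_segment(800, eps = p$eps, map = "A", location = 1),
    protocol_segment(800, eps = 0),
    protocol_segment(800, eps = p$eps, map = "A", location = 1))
  tr <- integrate_mf(op0, p, prot, t_end = 2400)
  expect_lt(abs(tr$x_phi[nrow(tr)]), 0.05 * max(h, 0.05))
})

test_that("slow morph: transition ordering and correlation readout", {
  mD <- slow_morph_protocol(regime_presets("double_ring"), "two_maps",
                            seed = 4)
  mC <- slow_morph_protocol(regime_presets("cylinder"), "two_maps", seed = 4)
  T_half <- 10000
  # double ring: sharp mu transition near (slightly after) mid-morph
  expect_gt(mD$transition$time_mu, 0.4 * 2 * T_half)
  expect_lt(mD$transition$time_mu, 0.7 * 2 * T_half)
  # cylinder transition happens later than the double-ring one
  expect_gt(mC$transition$time_x_phi, mD$transition$time_mu)
  # correlation traces start aligned with A and end aligned with B
  expect_gt(mD$corr$corr_A[2], 0.9)
  nl <- nrow(mC$corr)
  expect_gt(mC$corr$corr_B[nl], 0.8)
  expect_true(all(stats::na.omit(c(mD$corr$corr_A, mD$corr$corr_B)) <= 1 + 1e-9))
})

test_that("full-morph storage runs in the finite network and ends in map B", {
  # desk-scale smoke of the full_morph mode: a small network storing a few
  # morph maps, short morph; the activity must end correlated with the
  # environment-B reference
  p <- model_params(d = 1, J_mod = 6, J_inh = 8, eps = 0.2)
  mm <- slow_morph_protocol(p, "full_morph", T_morph = 3000, n_morph_maps = 9,
                            N = 150, seed = 2)
  expect_equal(mm$mode, "full_morph")
  n <- nrow(mm$corr)
  expect_gt(mean(mm$corr$corr_B[(n - 10):n], na.rm = TRUE),
            mean(mm$corr$corr_A[(n - 10):n], na.rm = TRUE))
  expect_true(all(stats::na.omit(unlist(mm$corr[, -1])) <= 1 + 1e-9))
})

test_that("activity correlation timecourse: trivial and piecewise cases", {
  set.seed(2)
  refA <- matrix(stats::runif(40 * 30), 40)
  refB <- matrix(stats::runif(40 * 30), 40)
  # run identical to refA: trace is 1 (to rounding)
  tc <- activity_correlation_timecourse(refA, refA, refB)
  expect_equal(tc$corr_A, rep(1, 40), tolerance = 1e-12)
  # piecewise-identical run: step between the two traces
  run <- rbind(refA[1:20, ], refB[21:40, ])
  tc2 <- activity_correlation_timecourse(run, refA, refB)
  expect_equal(tc2$corr_A[1:20], rep(1, 20), tolerance = 1e-12)
  expect_equal(tc2$corr_B[21:40], rep(1, 20), tolerance = 1e-12)
  # zero-variance frame flagged undefined
  run[5, ] <- 1
  tc3 <- activity_correlation_timecourse(run, refA, refB)
  expect_true(is.na(tc3$corr_A[5]))
})
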
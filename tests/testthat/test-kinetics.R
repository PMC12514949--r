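# Forward model: transition matrix, simulation, noise, normalization.

test_that("closed-form transition matrix matches the numeric matrix exponential", {
  # nominal regime, frozen entry
  p <- nominal_params()
  G <- transition_matrix(p, 2)
  expect_equal(G[1, 1], exp(-(0.0135 + 1 / 35) * 2), tolerance = 1e-12)
  expect_equal(unname(G), expm_oracle(p, 2), tolerance = 1e-10)

  # random grid of valid rates, including near-degenerate combinations
  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    if (i %% 5 == 0) p$R1P <- p$k + p$R1S + runif(1, -1e-7, 1e-7)
    TR <- runif(1, 0.25, 10)
    expect_lt(max(abs(unname(transition_matrix(p, TR)) -
                        expm_oracle(p, TR))), 1e-10)
  }

  # exact degeneracy R1P = k + R1S
  p <- kin_params(k = 0.01, R1S = 0.02, R1P = 0.03, S0 = 1, P0 = 0)
  expect_lt(max(abs(unname(transition_matrix(p, 2)) - expm_oracle(p, 2))),
            1e-10)
})

test_that("transition matrix approaches identity as all rates vanish", {
  p <- kin_params(k = 0, R1S = 1e-12, R1P = 1e-12, S0 = 1, P0 = 0)
  expect_equal(unname(transition_matrix(p, 5)), diag(2), tolerance = 1e-10)
})

test_that("transition matrix rejects invalid rates", {
  expect_error(kin_params(k = -0.1, R1S = 0.1, R1P = 0.1, S0 = 1, P0 = 0),
               "k must be")
  expect_error(kin_params(k = 0.1, R1S = 0, R1P = 0.1, S0 = 1, P0 = 0),
               "R1S")
  p <- nominal_params()
  expect_error(transition_matrix(p, -1))
})

test_that("simulation reduces to pure relaxation when no pulse is played", {
  p <- nominal_params()
  sc <- flip_scheme(rep(0, 6), TR = 2)
  traj <- simulate_trajectory(p, sc)
  expect_true(all(traj$y == 0))
  G <- transition_matrix(p, 2)
  x_expect <- c(p$S0, p$P0)
  for (t in 1:6) {
    expect_equal(unname(traj$x[, t]), x_expect, tolerance = 1e-12)
    x_expect <- as.vector(G %*% x_expect)
  }
})

test_that("a 90-degree first pulse converts everything to signal", {
  p <- nominal_params()
  sc <- flip_scheme(c(90, 30, 30), TR = 2)
  traj <- simulate_trajectory(p, sc)
  expect_equal(unname(traj$y[, 1]), c(p$S0, p$P0), tolerance = 1e-12)
  expect_equal(unname(traj$x[, 2]), c(0, 0), tolerance = 1e-12)
  expect_true(all(abs(traj$y[, -1]) < 1e-12))
})

test_that("simulation matches an independent step-by-step recursion", {
  p <- nominal_params()
  sc <- flip_scheme(c(30, 30), TR = 2)
  traj <- simulate_trajectory(p, sc)
  # hand-rolled recursion with scalar arithmetic
  a <- 30 * pi / 180
  G <- expm_oracle(p, 2)
  x0 <- c(p$S0, p$P0)
  y0 <- sin(a) * x0
  x1 <- G %*% (cos(a) * x0)
  y1 <- sin(a) * x1
  expect_equal(unname(traj$y[, 1]), y0, tolerance = 1e-12)
  expect_equal(unname(traj$y[, 2]), as.vector(y1), tolerance = 1e-10)
  expect_equal(unname(traj$x[, 2]), as.vector(x1), tolerance = 1e-10)
})

test_that("total longitudinal magnetization never increases", {
  set.seed(7)
  for (i in 1:10) {
    p <- random_params()
    sc <- random_scheme(n = 15)
    traj <- simulate_trajectory(p, sc)
    # compare state after excitation loss + relaxation with state before
    tot <- colSums(traj$x)
    loss <- cos(sc$angles * pi / 180)
    # x_{t+1} cannot exceed what survived the pulse at t
    for (t in seq_len(length(tot) - 1)) {
      expect_lte(tot[t + 1], loss[t] * tot[t] + 1e-12)
    }
  }
})

test_that("a unit B1 scale reproduces the variant without B1", {
  p1 <- nominal_params()
  p2 <- nominal_params(B1S = 1)
  sc <- random_scheme(n = 10)
  expect_identical(simulate_trajectory(p1, sc)$y,
                   simulate_trajectory(p2, sc)$y)
})

test_that("noise injection is reproducible and unbiased in scale", {
  p <- nominal_params()
  sc <- cfa_scheme(13.5, 20)
  traj <- normalize_signals(simulate_trajectory(p, sc))
  d1 <- add_noise(traj, 5e-3, seed = 99)
  d2 <- add_noise(traj, 5e-3, seed = 99)
  expect_identical(d1$signals, d2$signals)

  # near-zero noise reproduces the noiseless backbone
  d0 <- add_noise(traj, 1e-14, seed = 1)
  expect_equal(d0$signals, traj$y, tolerance = 1e-12)

  # empirical sd over many draws matches the requested level within 1%
  big <- vfadesign:::draw_standard_noise(20, 2500, seed = 5)
  expect_equal(sd(big) * 5e-3, 5e-3, tolerance = 0.01)
})

test_that("normalization modes agree on noiseless data and differ only via
           the first-point noise on noisy data", {
  p <- nominal_params()
  sc <- cfa_scheme(13.5, 15)
  traj <- simulate_trajectory(p, sc)
  n1 <- normalize_signals(traj, "first-point")
  n2 <- normalize_signals(traj, "s0-sina0")
  expect_equal(n1$y, n2$y, tolerance = 1e-12)
  expect_equal(unname(n1$y[1, 1]), 1, tolerance = 1e-12)

  # scale invariance: doubling S0 rescales away entirely when P0 = 0
  p0 <- kin_params(k = p$k, R1S = p$R1S, R1P = p$R1P, S0 = 5, P0 = 0)
  pd <- kin_params(k = p$k, R1S = p$R1S, R1P = p$R1P, S0 = 10, P0 = 0)
  expect_equal(normalize_signals(simulate_trajectory(p0, sc), "s0-sina0")$y,
               normalize_signals(simulate_trajectory(pd, sc), "s0-sina0")$y,
               tolerance = 1e-12)

  # noisy: the two factors differ exactly by the noise realized on the
  # first substrate point
  ds <- add_noise(traj, 0.01, seed = 3)
  f1 <- ds$signals[1, 1]                  # first-point divisor
  f2 <- p$S0 * sin(13.5 * pi / 180)       # model divisor
  m1 <- normalize_signals(ds, "first-point")
  m2 <- normalize_signals(ds, "s0-sina0")
  expect_equal(m1$signals * f1, m2$signals * f2, tolerance = 1e-12)

  # degenerate: first angle 0
  sc0 <- flip_scheme(c(0, 30, 30), 2)
  expect_error(normalize_signals(simulate_trajectory(p, sc0)),
               "degenerate normalization")
})
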
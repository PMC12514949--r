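# Monte Carlo harnesses, agreement analysis, fixture generation.

sparse_scheme <- function() {
  flip_scheme(c(28, 0, 0, 0, 0, 25, 30, 35, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                0, 0, 0, 0, 0, 60, 75, 90, 90), 2)
}

test_that("Monte Carlo recovery is bit-reproducible under a fixed seed", {
  sc <- sparse_scheme()
  p <- nominal_params()
  m1 <- mc_distribution(sc, p, 5e-3, 10, seed = 17)
  m2 <- mc_distribution(sc, p, 5e-3, 10, seed = 17)
  expect_identical(m1$estimates, m2$estimates)
  expect_identical(m1$sd, m2$sd)
})

test_that("vanishing noise collapses the estimate distribution", {
  m <- mc_distribution(sparse_scheme(), nominal_params(), 1e-8, 5, seed = 2)
  expect_true(all(m$sd < 1e-6))
  expect_equal(m$n_excluded, 0)
})

test_that("summary statistics satisfy the RMSE decomposition", {
  m <- mc_distribution(sparse_scheme(), nominal_params(), 5e-3, 40, seed = 5)
  n <- m$n_reps
  expect_equal(m$rmse^2, m$bias^2 + m$sd^2 * (n - 1) / n, tolerance = 1e-10)
})

test_that("the robustness sweep's unit-multiplier column reproduces the
           plain recovery study", {
  p <- nominal_params()
  schemes <- list(cfa = cfa_scheme(13.5, 28), vfa = sparse_scheme())
  sw <- mc_robustness_sweep(schemes, p, 5e-3, n_reps = 25, seed = 9,
                            vary = "k", multipliers = c(0.75, 1),
                            reference = "cfa")
  noise <- vfadesign:::draw_standard_noise(28, 25, seed = 9)
  direct <- mc_distribution(sparse_scheme(), p, 5e-3, 25, noise = noise)
  cell <- sw[sw$scheme == "vfa" & sw$multiplier == 1, ]
  expect_equal(cell$rmse_k, direct$rmse[["k"]], tolerance = 1e-12)
  expect_equal(sw$dlog10_rmse_k[sw$scheme == "cfa"], c(0, 0))
})

test_that("a fixed B1 draw reduces the B1-variation study to the plain
           recovery study", {
  p <- nominal_params()
  sc <- sparse_scheme()
  noise <- vfadesign:::draw_standard_noise(28, 20, seed = 4)
  b1 <- mc_b1_variation(sc, p, b1_sd = 0, sigma = 5e-3, n_reps = 20,
                        fit_variants = "with-b1s", seed = 4, noise = noise)
  direct <- mc_distribution(sc, p, 5e-3, 20, variant = "with-b1s",
                            noise = noise)
  expect_equal(b1[["with-b1s"]]$estimates, direct$estimates,
               tolerance = 1e-12)
})

test_that("ignoring true B1 variation inflates relaxation-rate scatter", {
  p <- nominal_params()
  sc <- sparse_scheme()
  noise <- vfadesign:::draw_standard_noise(28, 60, seed = 8)
  varying <- mc_b1_variation(sc, p, b1_sd = 0.15, sigma = 5e-3, n_reps = 60,
                             fit_variants = "without-b1s", seed = 8,
                             noise = noise)
  fixed <- mc_distribution(sc, p, 5e-3, 60, noise = noise)
  expect_gt(varying[["without-b1s"]]$sd[["R1S"]], 2 * fixed$sd[["R1S"]])
  expect_gt(varying[["without-b1s"]]$sd[["R1P"]], 2 * fixed$sd[["R1P"]])
})

test_that("the semi-synthetic study on a simulated backbone reduces to the
           plain recovery study", {
  p <- nominal_params()
  sc <- sparse_scheme()
  noise <- vfadesign:::draw_standard_noise(28, 15, seed = 6)
  backbone <- as_dataset(normalize_signals(simulate_trajectory(p, sc),
                                           mode = "s0-sina0"), 5e-3)
  a0 <- sc$angles[1] * pi / 180
  C <- p$S0 * sin(a0)
  # equal effective noise: semisynthetic divides sigma by sin(alpha0), the
  # raw-noise pipeline divides by the full normalization factor
  semi <- semisynthetic(backbone, sc, sigma = 5e-3 / p$S0, n_reps = 15,
                        seed = 6, noise = noise)
  direct <- mc_distribution(sc, p, 5e-3, 15, noise = noise)
  # sigma is composed in a different floating-point order in the two paths,
  # so agreement is at fit precision rather than bit level
  expect_equal(semi$estimates, direct$estimates, tolerance = 1e-6)
})

test_that("a drifting-rate backbone shifts the Monte Carlo mean exactly as
           it shifts the noiseless fit", {
  p <- nominal_params()
  sc <- sparse_scheme()
  mm <- vfadesign:::mismatch_trajectory(p, sc)
  ds <- as_dataset(mm, 5e-3)
  noiseless_fit <- fit_kinetics(ds, sc)
  semi <- semisynthetic(ds, sc, sigma = 1e-3, n_reps = 60, seed = 12,
                        noise_scale = "none", truth = p)
  sem <- semi$sd[["k"]] / sqrt(semi$n_reps)
  expect_lt(abs(semi$mean[["k"]] - noiseless_fit$estimates$k), 3 * sem)
  # the deterministic mismatch biases k low relative to the nominal rate
  expect_lt(noiseless_fit$estimates$k, p$k)
})

test_that("Bland-Altman agreement handles identity, offsets and mismatches", {
  ba <- bland_altman(1:10, 1:10)
  expect_equal(ba$bias, 0)
  expect_equal(ba$limits, c(0, 0))
  ba2 <- bland_altman((1:10) + 0.5, 1:10)
  expect_equal(ba2$bias, 0.5)
  expect_equal(ba2$limits, c(0.5, 0.5))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("fixture generation is deterministic and round-trips through the
           fitting pipeline", {
  p <- nominal_params()
  schemes <- list(cfa_k = cfa_scheme(13.5, 28), vfa_k = sparse_scheme())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_fixtures(d1, schemes, p, seed = 3)
  f2 <- generate_fixtures(d2, schemes, p, seed = 3)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # constant excitation drains the substrate monotonically
  cfa_traj <- read_dataset(file.path(d1, "cfa_k_noiseless.csv"))
  expect_true(all(diff(cfa_traj$signals[1, ]) < 0))
  # noiseless fixtures recover the nominal parameters
  ds <- read_dataset(file.path(d1, "vfa_k_noiseless.csv"))
  f <- fit_kinetics(ds)
  expect_lt(abs(f$estimates$k - p$k) / p$k, 1e-6)
  # the miscalibrated-B1 fixture fits back to B1S = 0.85
  dsb <- read_dataset(file.path(d1, "vfa_k_b1_085.csv"))
  fb <- fit_kinetics(dsb, variant = "with-b1s")
  expect_lt(abs(fb$estimates$B1S - 0.85), 1e-4)
})
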
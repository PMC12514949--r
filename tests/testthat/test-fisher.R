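# Sensitivities, Fisher information, Cramér-Rao bounds, L-optimality.

test_that("transition-matrix gradients match finite differences", {
  p <- nominal_params()
  TR <- 2
  dG <- transition_matrix_grad(p, TR)
  th <- c(p$k, p$R1S, p$R1P)
  Gfun <- function(v) {
    q <- kin_params(k = v[1], R1S = v[2], R1P = v[3], S0 = p$S0, P0 = p$P0)
    as.vector(transition_matrix(q, TR))
  }
  for (i in 1:3) {
    fd <- fd_derivative(Gfun, th, i)
    expect_equal(as.vector(dG[[i]]), fd, tolerance = 1e-5)
  }
  # degenerate-rate limit stays consistent with finite differences
  pd <- kin_params(k = 0.01, R1S = 0.02, R1P = 0.030000001, S0 = 1, P0 = 0)
  dGd <- transition_matrix_grad(pd, TR)
  thd <- c(pd$k, pd$R1S, pd$R1P)
  Gfun_d <- function(v) {
    q <- kin_params(k = v[1], R1S = v[2], R1P = v[3], S0 = 1, P0 = 0)
    as.vector(transition_matrix(q, TR, degeneracy_tol = 0))
  }
  for (i in 1:3) {
    expect_equal(as.vector(dGd[[i]]), fd_derivative(Gfun_d, thd, i, h = 1e-5),
                 tolerance = 1e-4)
  }
})

test_that("k = 0 limit of the conversion-entry derivative has its closed form", {
  p <- kin_params(k = 0, R1S = 1 / 35, R1P = 1 / 54, S0 = 1, P0 = 0)
  TR <- 2
  dG <- transition_matrix_grad(p, TR)
  analytic <- (exp(-p$R1S * TR) - exp(-p$R1P * TR)) / (p$R1P - p$R1S)
  expect_equal(dG$k[2, 1], analytic, tolerance = 1e-10)
})

test_that("analytic signal sensitivities match finite differences of the
           simulate-then-normalize pipeline", {
  set.seed(11)
  for (case in 1:5) {
    with_b1 <- case %% 2 == 0
    p <- random_params(with_b1 = with_b1)
    sc <- random_scheme(n = 10)
    sc$angles[1] <- max(sc$angles[1], 5)  # keep normalization well-defined
    C <- p$S0 * sin(deg2rad_test(sc$angles[1]) * (p$B1S %||% 1))
    variant <- if (with_b1) "with-b1s" else "without-b1s"
    s <- sensitivities(p, sc, variant, normalization = C)
    th <- c(p$k, p$R1S, p$R1P, p$S0, p$P0)
    if (with_b1) th <- c(th, p$B1S)
    f <- function(v) {
      q <- kin_params(k = v[1], R1S = v[2], R1P = v[3], S0 = v[4], P0 = v[5],
                      B1S = if (with_b1) v[6] else NULL)
      as.vector(simulate_trajectory(q, sc)$y) / C
    }
    for (i in seq_along(th)) {
      fd <- fd_derivative(f, th, i)
      denom <- pmax(abs(fd), max(abs(fd)) * 1e-3 + 1e-12)
      expect_lt(max(abs(s$dy[, i] - fd) / denom), 1e-5)
    }
  }
})

test_that("zero-angle schemes carry no sensitivity and zero information", {
  p <- nominal_params()
  sc <- flip_scheme(rep(0, 8), 2)
  s <- sensitivities(p, sc)
  expect_true(all(s$dy == 0))
  fr <- fim(p, sc, 5e-3)
  expect_true(all(fr$matrix == 0))
  expect_false(fr$invertible)
  expect_error(crlb(fr), "singular")
})

test_that("initial-state sensitivity at t = 0 reflects linearity in P0", {
  p <- kin_params(k = 0.0135, R1S = 1 / 35, R1P = 1 / 54, S0 = 5, P0 = 0)
  sc <- cfa_scheme(20, 5)
  C <- p$S0 * sin(deg2rad_test(20))
  s <- sensitivities(p, sc, normalization = C)
  expect_equal(unname(s$dy[2, "P0"]), sin(deg2rad_test(20)) / C,
               tolerance = 1e-12)
  expect_equal(unname(s$dy[1, "P0"]), 0)
})

test_that("Fisher information is symmetric PSD and scales as 1/sigma^2", {
  set.seed(13)
  for (i in 1:5) {
    p <- random_params()
    sc <- random_scheme(n = 12)
    fr <- fim(p, sc, 5e-3)
    expect_equal(fr$matrix, t(fr$matrix), tolerance = 1e-10)
    ev <- eigen(fr$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10 * sum(diag(fr$matrix))))
    fr2 <- fim(p, sc, 5e-3 * 3)
    expect_equal(fr2$matrix, fr$matrix / 9, tolerance = 1e-10)
  }
})

test_that("turning on the final excitation never reduces diagonal information", {
  # an extra pulse mid-sequence consumes magnetization and can degrade later
  # measurements; the last excitation has no later measurements to spoil, so
  # it can only add information
  p <- nominal_params()
  ang <- c(20, 0, 15, 0, 30, 10, 0)
  base <- fim(p, flip_scheme(ang, 2), 5e-3)
  for (a_last in c(10, 45, 90)) {
    ang2 <- ang
    ang2[7] <- a_last
    more <- fim(p, flip_scheme(ang2, 2), 5e-3)
    expect_true(all(diag(more$matrix) >= diag(base$matrix) - 1e-15))
  }
})

test_that("a constant-angle scheme makes the B1 scale unidentifiable", {
  p <- nominal_params(B1S = 1)
  fr <- fim(p, cfa_scheme(13.5), 5e-3, variant = "with-b1s")
  expect_false(fr$invertible)
  # a variable scheme restores identifiability
  sc <- flip_scheme(c(25, 5, 35, 0, 15, 45, 10, 60, 20, 90), 2)
  expect_true(fim(p, sc, 5e-3, variant = "with-b1s")$invertible)
})

test_that("Cramér-Rao bound is the information inverse", {
  p <- nominal_params()
  sc <- cfa_scheme(13.5, 30)
  fr <- fim(p, sc, 5e-3)
  cb <- crlb(fr)
  expect_equal(unname(cb %*% fr$matrix), diag(5), tolerance = 1e-8)
})

test_that("L-optimality equals a brute-force weighted trace and reduces to
           A-optimality under unit weights", {
  p <- nominal_params()
  sc <- cfa_scheme(13.5, 30)
  fr <- fim(p, sc, 5e-3, scale = "nondimensional")
  w <- weight_spec(k = 2, R1S = 0.5, R1P = 1.25)
  # independent linear-algebra path: explicit W, qr-based inverse, trace
  W <- diag(c(2, 0.5, 1.25, 0, 0))
  brute <- sum(diag(W %*% qr.solve(fr$matrix)))
  expect_equal(l_optimality(fr, w), brute, tolerance = 1e-10)
  expect_equal(l_optimality(fr, weight_spec()), 0)
  a_opt <- l_optimality(fr, weight_spec(k = 1, R1S = 1, R1P = 1, S0 = 1,
                                        P0 = 1))
  expect_equal(a_opt, sum(diag(crlb(fr))), tolerance = 1e-12)
  expect_error(l_optimality(fr, weight_spec(B1S = 1)), "absent")
})

test_that("non-dimensionalization scales rates by TR and round-trips", {
  p <- nominal_params()
  nd <- nondimensionalize(p, TR = 2)
  expect_equal(unname(nd$theta["k"]), 0.027, tolerance = 1e-12)
  back <- redimensionalize(nd)
  for (f in c("k", "R1S", "R1P", "S0", "P0")) {
    expect_equal(back[[f]], p[[f]], tolerance = 1e-14)
  }
})

test_that("the design ranking of schemes is invariant to the noise level", {
  p <- nominal_params()
  w <- design_weights(p)
  prior <- make_b1_prior()
  angs <- c(8, 13.5, 25)
  vals1 <- vapply(angs, function(a)
    design_objective(rep(a, 40), p, w, prior,
                     design_config(sigma = 5e-3), lambda = 0), numeric(1))
  vals2 <- vapply(angs, function(a)
    design_objective(rep(a, 40), p, w, prior,
                     design_config(sigma = 0.05), lambda = 0), numeric(1))
  expect_identical(order(vals1), order(vals2))
  expect_equal(vals2 / vals1, rep(100, 3), tolerance = 1e-9)
})
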
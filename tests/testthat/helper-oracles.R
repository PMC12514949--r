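# Shared oracle utilities: finite differences, random valid parameter sets,
# numeric matrix exponential.

# central finite-difference derivative of f (vector-valued) in theta[i]
fd_derivative <- function(f, theta, i, h = NULL) {
  h <- h %||% (abs(theta[i]) * 1e-6 + 1e-10)
  up <- theta; up[i] <- up[i] + h
  dn <- theta; dn[i] <- dn[i] - h
  (f(up) - f(dn)) / (2 * h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random valid kinetic parameter set (seeded by the caller)
random_params <- function(with_b1 = FALSE) {
  kin_params(k = runif(1, 1e-3, 0.1),
             R1S = runif(1, 1 / 80, 1 / 10),
             R1P = runif(1, 1 / 80, 1 / 10),
             S0 = runif(1, 0.5, 10),
             P0 = runif(1, 0, 0.5),
             B1S = if (with_b1) runif(1, 0.6, 1.4) else NULL)
}

random_scheme <- function(n = 12, TR = 2) {
  flip_scheme(runif(n, 0, 90), TR)
}

# numeric matrix exponential oracle (scaling-and-squaring via Matrix)
expm_oracle <- function(params, TR) {
  A <- matrix(c(-(params$k + params$R1S), params$k, 0, -params$R1P), 2, 2)
  unname(as.matrix(Matrix::expm(TR * A)))
}

deg2rad_test <- function(x) x * pi / 180

nominal_sigma <- 5e-3
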
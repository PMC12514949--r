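# Forward model: kinetic parameters, flip-angle schemes, magnetization
# propagation between excitations, signal generation, noise, normalization.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kinetic parameter set for the two-metabolite conversion model
#'
#' Bundles the parameters of the unidirectional substrate-to-product
#' conversion model: the apparent first-order conversion rate `k`, the
#' longitudinal relaxation rates `R1S` and `R1P` (1/T1) of substrate and
#' product, the initial longitudinal magnetizations `S0` and `P0`, and
#' optionally the dimensionless transmit-field scale `B1S` relating
#' prescribed to delivered flip angles.
#'
#' @param k Conversion rate, 1/s (>= 0).
#' @param R1S Substrate longitudinal relaxation rate, 1/s (> 0).
#' @param R1P Product longitudinal relaxation rate, 1/s (> 0).
#' @param S0 Initial substrate longitudinal magnetization, arbitrary units (> 0).
#' @param P0 Initial product longitudinal magnetization (>= 0).
#' @param B1S Optional flip-angle scale (> 0). `NULL` selects the model
#'   variant without a B1 parameter (equivalent to `B1S = 1` in simulation).
#' @return An object of class `kin_params`.
#' @examples
#' kin_params(k = 0.0135, R1S = 1/35, R1P = 1/54, S0 = 5, P0 = 0.1)
#' @export
kin_params <- function(k, R1S, R1P, S0, P0, B1S = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k < 0) stop("k must be >= 0")
  if (!is.numeric(R1S) || R1S <= 0) stop("R1S must be > 0")
  if (!is.numeric(R1P) || R1P <= 0) stop("R1P must be > 0")
  if (!is.numeric(S0) || S0 <= 0) stop("S0 must be > 0")
  if (!is.numeric(P0) || P0 < 0) stop("P0 must be >= 0")
  if (!is.null(B1S) && (!is.numeric(B1S) || B1S <= 0)) stop("B1S must be > 0")
  structure(list(k = as.numeric(k), R1S = as.numeric(R1S),
                 R1P = as.numeric(R1P), S0 = as.numeric(S0),
                 P0 = as.numeric(P0),
                 B1S = if (is.null(B1S)) NULL else as.numeric(B1S)),
            class = "kin_params")
}

#' @export
print.kin_params <- function(x, ...) {
  cat("Kinetic parameters (two-metabolite unidirectional conversion)\n")
  cat(sprintf("  k   = %.6g 1/s   (T = %.4g s)\n", x$k,
              if (x$k > 0) 1 / x$k else Inf))
  cat(sprintf("  R1S = %.6g 1/s   (T1S = %.4g s)\n", x$R1S, 1 / x$R1S))
  cat(sprintf("  R1P = %.6g 1/s   (T1P = %.4g s)\n", x$R1P, 1 / x$R1P))
  cat(sprintf("  S0  = %.6g, P0 = %.6g\n", x$S0, x$P0))
  if (!is.null(x$B1S)) cat(sprintf("  B1S = %.6g\n", x$B1S))
  invisible(x)
}

#' Nominal parameter values of the in-vitro model system
#'
#' The ethyl acetoacetate (substrate) to acetoacetate (product) conversion
#' catalyzed by carboxyl esterase, at the enzyme concentration and field used
#' throughout the package examples: `k = 0.0135` 1/s, `T1S = 35` s,
#' `T1P = 54` s, `S0 = 5`, `P0 = 0.1`.
#'
#' @param rate_multiplier Multiplies `k`, `R1S` and `R1P` jointly; a value of
#'   1.5 gives the deliberately mis-specified parameter set used to study
#'   designs optimized for the wrong nominal rates.
#' @param B1S Optional flip-angle scale passed through to [kin_params()].
#' @return A `kin_params` object.
#' @export
nominal_params <- function(rate_multiplier = 1, B1S = NULL) {
  kin_params(k = 0.0135 * rate_multiplier,
             R1S = rate_multiplier / 35,
             R1P = rate_multiplier / 54,
             S0 = 5, P0 = 0.1, B1S = B1S)
}

# numeric parameter vector (k, R1S, R1P, S0, P0) and the simulation B1 scale
theta_vector <- function(params) {
  c(params$k, params$R1S, params$R1P, params$S0, params$P0)
}

b1_scale <- function(params) params$B1S %||% 1

param_names <- function(variant = c("without-b1s", "with-b1s")) {
  variant <- match.arg(variant)
  if (variant == "with-b1s") c("k", "R1S", "R1P", "S0", "P0", "B1S")
  else c("k", "R1S", "R1P", "S0", "P0")
}

#' Flip-angle scheme on a uniform TR grid
#'
#' A prescribed excitation schedule: one flip angle per repetition period,
#' sampled at `t = 0, TR, ..., N*TR`.
#'
#' @param angles_deg Prescribed flip angles in degrees, each in \[0, 90\].
#' @param TR Repetition time in seconds (> 0).
#' @return An object of class `flip_scheme` with elements `angles` (degrees),
#'   `TR` and `times` (seconds).
#' @seealso [cfa_scheme()] for a constant-angle scheme.
#' @export
flip_scheme <- function(angles_deg, TR) {
  stopifnot(is.numeric(angles_deg), length(angles_deg) >= 1L,
            is.numeric(TR), length(TR) == 1L)
  if (TR <= 0) stop("TR must be > 0")
  if (any(!is.finite(angles_deg)) || any(angles_deg < 0) ||
      any(angles_deg > 90)) {
    stop("flip angles must lie in [0, 90] degrees")
  }
  angles_deg <- as.numeric(angles_deg)
  structure(list(angles = angles_deg, TR = as.numeric(TR),
                 times = (seq_along(angles_deg) - 1L) * as.numeric(TR)),
            class = "flip_scheme")
}

#' Constant flip-angle (CFA) scheme
#'
#' @param angle_deg The constant flip angle in degrees.
#' @param n_angles Number of excitations (default 91, i.e. t = 0..180 s at
#'   TR = 2 s, the horizon used throughout the package's design examples).
#' @param TR Repetition time in seconds.
#' @return A `flip_scheme`.
#' @export
cfa_scheme <- function(angle_deg, n_angles = 91L, TR = 2) {
  flip_scheme(rep(angle_deg, n_angles), TR)
}

#' @export
print.flip_scheme <- function(x, ...) {
  nz <- sum(x$angles > 0)
  cat(sprintf("Flip-angle scheme: %d excitations, TR = %g s (%g s total)\n",
              length(x$angles), x$TR, max(x$times)))
  cat(sprintf("  %d non-zero angles; range %.2f-%.2f deg\n",
              nz, min(x$angles), max(x$angles)))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180

#' Transition matrix over one repetition period
#'
#' Closed form of `expm(TR * A)` for the kinetic generator
#' `A = [[-(k+R1S), 0], [k, -R1P]]`, which propagates the longitudinal
#' magnetization of (substrate, product) over one TR of relaxation and
#' conversion: `G11 = exp(-(k+R1S) TR)`, `G22 = exp(-R1P TR)` and
#' `G21 = k (G11 - G22) / (R1P - k - R1S)`, switching to the series limit
#' `G21 = k TR G11` when `|R1P - k - R1S|` falls below `degeneracy_tol`
#' (avoids catastrophic cancellation at the defective-eigenvalue point).
#'
#' @param params A [kin_params()] object.
#' @param TR Repetition time in seconds (> 0).
#' @param degeneracy_tol Rate-difference threshold (1/s) below which the
#'   limiting form of the off-diagonal entry is used.
#' @return A 2 x 2 lower-triangular matrix.
#' @export
transition_matrix <- function(params, TR, degeneracy_tol = 1e-8) {
  stopifnot(inherits(params, "kin_params"), TR > 0)
  k <- params$k; a <- params$k + params$R1S; r1p <- params$R1P
  g11 <- exp(-a * TR)
  g22 <- exp(-r1p * TR)
  d <- r1p - a
  g21 <- if (abs(d) < degeneracy_tol) k * TR * g11 else k * (g11 - g22) / d
  matrix(c(g11, g21, 0, g22), 2, 2,
         dimnames = list(c("S", "P"), c("S", "P")))
}

#' Simulate the noiseless dynamic experiment
#'
#' Runs the discrete-time hybrid model: starting from `x0 = (S0, P0)`, each
#' excitation at prescribed angle `alpha_t` converts `sin(B1S * alpha_t)` of
#' the longitudinal magnetization into measurable transverse signal, leaves
#' `cos(B1S * alpha_t)` behind, and the remainder relaxes and converts over
#' one TR according to the transition matrix.
#'
#' @param params A [kin_params()] object; a non-`NULL` `B1S` scales every
#'   delivered angle.
#' @param scheme A [flip_scheme()].
#' @return An object of class `hp_trajectory` with `x` (2 x N+1 longitudinal
#'   magnetization immediately before each excitation), `y` (2 x N+1
#'   transverse signal), the generating `scheme` and `params`, and the
#'   `normalization` divisor applied so far (1 for raw simulations).
#' @export
simulate_trajectory <- function(params, scheme) {
  stopifnot(inherits(params, "kin_params"), inherits(scheme, "flip_scheme"))
  sim <- cpp_simulate(theta_vector(params), deg2rad(scheme$angles),
                      scheme$TR, b1_scale(params))
  rownames(sim$x) <- rownames(sim$y) <- c("substrate", "product")
  structure(list(x = sim$x, y = sim$y, scheme = scheme, params = params,
                 normalization = 1),
            class = "hp_trajectory")
}

#' @export
print.hp_trajectory <- function(x, ...) {
  cat(sprintf("Hyperpolarized trajectory: %d time points, TR = %g s\n",
              ncol(x$y), x$scheme$TR))
  cat(sprintf("  first signals: substrate %.4g, product %.4g; normalization %g\n",
              x$y[1, 1], x$y[2, 1], x$normalization))
  invisible(x)
}

effective_angles_rad <- function(scheme, params) {
  deg2rad(scheme$angles) * b1_scale(params)
}

normalization_factor <- function(obj, mode = c("first-point", "s0-sina0")) {
  mode <- match.arg(mode)
  scheme <- obj$scheme
  a0 <- scheme$angles[1]
  if (a0 <= 0) stop("degenerate normalization: first flip angle is 0 degrees")
  if (mode == "s0-sina0") {
    params <- obj$params
    if (is.null(params)) stop("s0-sina0 normalization requires generating parameters")
    params$S0 * sin(deg2rad(a0) * b1_scale(params))
  } else {
    sig <- if (inherits(obj, "hp_trajectory")) obj$y else obj$signals
    unname(sig[1, 1])
  }
}

#' Normalize signals by the first substrate measurement
#'
#' Divides all signals (and, for datasets, the noise standard deviation) by a
#' scalar calibration factor, mirroring the standard pre-analysis step of
#' dividing a dynamic series by its first substrate measure. Two modes are
#' offered: `"first-point"` uses the observed first substrate signal;
#' `"s0-sina0"` uses the model value `S0 * sin(B1S * alpha_0)`. On noiseless
#' data the two coincide exactly.
#'
#' @param obj An `hp_trajectory` or `hp_dataset`.
#' @param mode Normalization mode, see Details.
#' @return The same class of object with signals divided by the factor and
#'   the cumulative divisor recorded in `$normalization`.
#' @export
normalize_signals <- function(obj, mode = c("first-point", "s0-sina0")) {
  mode <- match.arg(mode)
  C <- normalization_factor(obj, mode)
  if (C <= 0) stop("degenerate normalization: non-positive factor")
  if (inherits(obj, "hp_trajectory")) {
    obj$x <- obj$x / C
    obj$y <- obj$y / C
  } else if (inherits(obj, "hp_dataset")) {
    obj$signals <- obj$signals / C
    obj$sigma <- obj$sigma / C
  } else {
    stop("normalize_signals expects an hp_trajectory or hp_dataset")
  }
  obj$normalization <- obj$normalization * C
  obj
}

#' Construct a dataset from a trajectory
#'
#' @param traj An `hp_trajectory` (typically normalized).
#' @param sigma Noise standard deviation per metabolite, on the scale of the
#'   stored signals; length 1 (shared) or 2.
#' @return An `hp_dataset` with `signals`, `sigma`, `normalization`,
#'   `included` (per-time-point fitting mask; `FALSE` exactly where the
#'   prescribed flip angle is 0), `scheme` and generating `params`.
#' @export
as_dataset <- function(traj, sigma) {
  stopifnot(inherits(traj, "hp_trajectory"))
  sigma <- check_sigma(sigma)
  structure(list(signals = traj$y, sigma = sigma,
                 normalization = traj$normalization,
                 included = traj$scheme$angles > 0,
                 scheme = traj$scheme, params = traj$params),
            class = "hp_dataset")
}

check_sigma <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) %in% c(1L, 2L))
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (length(sigma) == 1L) rep(as.numeric(sigma), 2L) else as.numeric(sigma)
}

#' @export
print.hp_dataset <- function(x, ...) {
  cat(sprintf("Dynamic dataset: %d time points, %d included for fitting\n",
              ncol(x$signals), sum(x$included)))
  cat(sprintf("  sigma = (%.3g, %.3g), normalization divisor = %.6g\n",
              x$sigma[1], x$sigma[2], x$normalization))
  invisible(x)
}

#' Add Gaussian measurement noise to a trajectory
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma` to
#' every signal value (both metabolites, all time points). Noise is applied on
#' the scale of the stored signals; in the standard pipeline the trajectory is
#' normalized first so the noise level is comparable across schemes.
#'
#' A pre-drawn standard-normal `noise` matrix may be supplied to reuse the
#' same realization across schemes of equal length (common random numbers).
#'
#' @param traj An `hp_trajectory` (or `hp_dataset`, whose signals are reused
#'   as the noiseless backbone).
#' @param sigma Noise standard deviation (length 1 or 2).
#' @param seed Integer seed used to draw the realization; ignored when
#'   `noise` is given.
#' @param noise Optional 2 x (N+1) matrix of standard-normal draws.
#' @return An `hp_dataset`.
#' @export
add_noise <- function(traj, sigma, seed = NULL, noise = NULL) {
  sigma <- check_sigma(sigma)
  ds <- if (inherits(traj, "hp_dataset")) traj else as_dataset(traj, sigma)
  nt <- ncol(ds$signals)
  if (is.null(noise)) {
    noise <- draw_standard_noise(nt, 1L, seed)[, , 1L]
  }
  stopifnot(is.matrix(noise), nrow(noise) == 2L, ncol(noise) == nt)
  ds$signals <- ds$signals + noise * sigma
  ds$sigma <- sigma
  ds
}

# Standard-normal noise cube (2 metabolites x n_time x n_reps), reproducible
# under an integer seed and shareable across schemes of equal length.
draw_standard_noise <- function(n_time, n_reps, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  array(rnorm(2L * n_time * n_reps), dim = c(2L, n_time, n_reps))
}
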
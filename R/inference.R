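# Maximum-likelihood (bounded least-squares) fitting of the kinetic model to
# normalized dynamic data, with or without the B1 scale parameter.

#' Default parameter bounds for model fitting
#'
#' Generous physical ranges around the regime of hyperpolarized conversion
#' experiments: `k` in \[0, 1\] 1/s, relaxation rates in \[1e-3, 1\] 1/s,
#' magnetizations in (0, 100\], `B1S` in \[0.3, 2\].
#'
#' @param variant `"without-b1s"` or `"with-b1s"`.
#' @return A list with numeric vectors `lower` and `upper` in the standard
#'   parameter order.
#' @export
default_fit_bounds <- function(variant = c("without-b1s", "with-b1s")) {
  variant <- match.arg(variant)
  lower <- c(k = 0, R1S = 1e-3, R1P = 1e-3, S0 = 1e-6, P0 = 0)
  upper <- c(k = 1, R1S = 1, R1P = 1, S0 = 100, P0 = 100)
  if (variant == "with-b1s") {
    lower <- c(lower, B1S = 0.3)
    upper <- c(upper, B1S = 2)
  }
  list(lower = lower, upper = upper)
}

#' Data-driven starting values for model fitting
#'
#' Constructs a rough parameter guess from a normalized dataset: `S0` and
#' `P0` from the first included signals divided by the sine of the first
#' effective angle (and multiplied back by the stored normalization), the
#' relaxation rates from the typical in-vitro values 1/35 and 1/54 1/s, and
#' `k` from the early product growth slope divided by the mean substrate
#' level, clipped to \[1e-4, 1\]. `B1S` starts at 1. The guess always
#' satisfies [default_fit_bounds()].
#'
#' @param dataset An `hp_dataset`.
#' @param scheme The generating [flip_scheme()] (defaults to the dataset's).
#' @return A [kin_params()] object with `B1S = 1`.
#' @export
initial_guess <- function(dataset, scheme = dataset$scheme) {
  stopifnot(inherits(dataset, "hp_dataset"), inherits(scheme, "flip_scheme"))
  a0 <- deg2rad(scheme$angles[1])
  if (a0 <= 0) stop("initial_guess requires a non-zero first flip angle")
  C <- dataset$normalization
  s0 <- dataset$signals[1, 1] * C / sin(a0)
  p0 <- dataset$signals[2, 1] * C / sin(a0)
  s0 <- min(max(s0, 1e-3), 100)
  p0 <- min(max(p0, 0), 100)

  # crude k: slope of the longitudinal product estimate over the early
  # included points, relative to the mean substrate level
  idx <- which(dataset$included & scheme$angles > 0)
  idx <- idx[seq_len(min(6L, length(idx)))]
  k_guess <- 1e-4
  if (length(idx) >= 2L) {
    sines <- sin(deg2rad(scheme$angles[idx]))
    prod_x <- dataset$signals[2, idx] * C / sines
    subs_x <- dataset$signals[1, idx] * C / sines
    tt <- scheme$times[idx]
    slope <- coef(lm(prod_x ~ tt))[2]
    denom <- mean(subs_x)
    if (is.finite(slope) && denom > 0) k_guess <- slope / denom
  }
  k_guess <- min(max(k_guess, 1e-4), 1)
  kin_params(k = unname(k_guess), R1S = 1 / 35, R1P = 1 / 54,
             S0 = unname(s0), P0 = unname(p0), B1S = 1)
}

#' Fit the kinetic model to a dynamic dataset
#'
#' Minimizes the sum of squared differences between the included observed
#' signals and the model prediction (divided by the dataset's stored
#' normalization) by bounded nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nls.lm()]) with the analytic residual
#' Jacobian from the sensitivity recursion. Under homoscedastic Gaussian
#' noise this is maximum-likelihood estimation. Points whose prescribed flip
#' angle is 0 carry no signal and are excluded.
#'
#' The `"with-b1s"` variant additionally frees the flip-angle scale; it is
#' refused for constant-angle schemes, where `B1S` is completely correlated
#' with `S0`, `P0`, `R1S` and `R1P` and cannot be identified.
#'
#' On non-convergence the fit is retried from a few deterministically
#' perturbed starting points before being returned flagged.
#'
#' @param dataset An `hp_dataset` (normalized in the standard pipeline).
#' @param scheme The [flip_scheme()] used for acquisition (defaults to the
#'   dataset's).
#' @param variant `"without-b1s"` (5 parameters) or `"with-b1s"` (6).
#' @param init Optional [kin_params()] starting point; defaults to
#'   [initial_guess()].
#' @param bounds Optional list with `lower`/`upper` named vectors; defaults
#'   to [default_fit_bounds()].
#' @param compute_covariance Also return the asymptotic covariance (inverse
#'   Fisher information at the estimate, using the dataset's sigma).
#' @return An object of class `fit_result`: `estimates` ([kin_params()]),
#'   `variant`, `residuals` (observed minus modeled on included points),
#'   `sse`, `converged`, `n_obs`, optional `covariance`.
#' @export
fit_kinetics <- function(dataset, scheme = dataset$scheme,
                         variant = c("without-b1s", "with-b1s"), init = NULL,
                         bounds = NULL, compute_covariance = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "hp_dataset"), inherits(scheme, "flip_scheme"))
  with_b1 <- variant == "with-b1s"
  p <- if (with_b1) 6L else 5L

  nz <- scheme$angles[scheme$angles > 0]
  if (with_b1 && length(unique(round(nz, 8))) <= 1L) {
    stop("identifiability error: B1S cannot be estimated from a ",
         "constant-angle scheme (completely correlated with S0, P0, R1S, R1P)")
  }
  inc <- dataset$included & scheme$angles > 0
  if (2L * sum(inc) < p) {
    stop("fewer included observations than free parameters")
  }
  bounds <- bounds %||% default_fit_bounds(variant)
  init <- init %||% initial_guess(dataset, scheme)
  th0 <- theta_vector(init)
  if (with_b1) th0 <- c(th0, init$B1S %||% 1)
  th0 <- pmin(pmax(th0, bounds$lower), bounds$upper)

  rad <- deg2rad(scheme$angles)
  C <- dataset$normalization
  rows <- as.vector(rbind(inc, inc))  # row mask in 2 x T column-major order
  obs <- as.vector(dataset$signals)[rows]

  resid_fn <- function(th) {
    b1 <- if (with_b1) th[6] else 1
    pred <- as.vector(cpp_simulate(th[1:5], rad, scheme$TR, b1)$y)[rows] / C
    obs - pred
  }
  jac_fn <- function(th) {
    b1 <- if (with_b1) th[6] else 1
    -cpp_sensitivities(th, rad, scheme$TR, b1, with_b1)[rows, , drop = FALSE] / C
  }

  run <- function(start) {
    minpack.lm::nls.lm(par = start, lower = bounds$lower,
                       upper = bounds$upper, fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-13, ptol = 1e-13))
  }
  fit <- run(th0)
  converged <- fit$info %in% 1:3
  if (!converged) {
    for (f in c(0.9, 1.1, 1.25)) {  # deterministic multistart, RNG untouched
      alt <- pmin(pmax(th0 * f, bounds$lower), bounds$upper)
      fit2 <- run(alt)
      if (fit2$info %in% 1:3) {
        fit <- fit2
        converged <- TRUE
        break
      }
      if (fit2$deviance < fit$deviance) fit <- fit2
    }
  }
  th <- fit$par
  est <- kin_params(k = th[1], R1S = th[2], R1P = th[3], S0 = th[4],
                    P0 = th[5], B1S = if (with_b1) th[6] else NULL)
  out <- structure(list(estimates = est, variant = variant,
                        residuals = resid_fn(th), sse = fit$deviance,
                        converged = converged, n_obs = 2L * sum(inc),
                        info = fit$info),
                   class = "fit_result")
  if (compute_covariance) {
    fr <- fim(est, scheme, dataset$sigma, variant,
              normalization = dataset$normalization)
    out$covariance <- if (fr$invertible) crlb(fr) else NULL
  }
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Kinetic model fit (%s): %s, SSE = %.4g on %d observations\n",
              x$variant, if (x$converged) "converged" else "NOT converged",
              x$sse, x$n_obs))
  e <- x$estimates
  cat(sprintf("  k = %.5g, R1S = %.5g, R1P = %.5g, S0 = %.4g, P0 = %.4g%s\n",
              e$k, e$R1S, e$R1P, e$S0, e$P0,
              if (!is.null(e$B1S)) sprintf(", B1S = %.4g", e$B1S) else ""))
  invisible(x)
}
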
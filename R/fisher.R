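# Analytic sensitivities, Fisher information, Cramér-Rao bounds,
# L-optimality and non-dimensionalization.

#' Parameter weights for L-optimal design
#'
#' A diagonal weight specification assigning importance to individual
#' parameter variances in the L-optimality criterion `tr(W * FIM^-1)`.
#' Weights act on the non-dimensionalized parameter scale, so a weight of
#' `1/theta_nd^2` turns the corresponding term into a squared relative
#' uncertainty.
#'
#' @param k,R1S,R1P,S0,P0 Nonnegative weights.
#' @param B1S Optional nonnegative weight; only meaningful for the model
#'   variant that carries a B1 scale parameter.
#' @return A named numeric vector of class `weight_spec`.
#' @seealso [design_weights()] for the conventional inverse-square weights.
#' @export
weight_spec <- function(k = 0, R1S = 0, R1P = 0, S0 = 0, P0 = 0, B1S = NULL) {
  w <- c(k = k, R1S = R1S, R1P = R1P, S0 = S0, P0 = P0)
  if (!is.null(B1S)) w <- c(w, B1S = B1S)
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be finite and >= 0")
  structure(w, class = "weight_spec")
}

n_weighted <- function(weights) sum(weights > 0)

#' Inverse-square design weights on the non-dimensionalized rates
#'
#' Builds the weight specification `1/theta_nd^2` for the requested rate
#' parameters, where `theta_nd = theta * TR` for the rates. With these
#' weights each L-optimality term is the squared relative uncertainty of the
#' corresponding rate, so rates of different magnitude are penalized on a
#' common scale.
#'
#' @param params A [kin_params()] object supplying the nominal values.
#' @param on Character vector naming the weighted rates, a subset of
#'   `c("k", "R1S", "R1P")`.
#' @param TR Repetition time used for non-dimensionalization, seconds.
#' @return A `weight_spec`.
#' @export
design_weights <- function(params, on = "k", TR = 2) {
  stopifnot(inherits(params, "kin_params"), all(on %in% c("k", "R1S", "R1P")))
  w <- weight_spec()
  for (nm in on) w[nm] <- 1 / (unlist(params[nm]) * TR)^2
  w
}

#' Partial derivatives of the transition matrix with respect to the rates
#'
#' Closed-form derivatives of each entry of the one-TR transition matrix with
#' respect to `k`, `R1S` and `R1P`, with series-limit handling at the
#' rate degeneracy `R1P = k + R1S`. The matrix does not depend on `S0`, `P0`
#' or `B1S`, so those derivatives are zero.
#'
#' @inheritParams transition_matrix
#' @return A list of three 2 x 2 matrices named `k`, `R1S`, `R1P`.
#' @export
transition_matrix_grad <- function(params, TR, degeneracy_tol = 1e-8) {
  stopifnot(inherits(params, "kin_params"), TR > 0)
  k <- params$k; a <- k + params$R1S; r1p <- params$R1P
  g11 <- exp(-a * TR)
  g22 <- exp(-r1p * TR)
  d <- r1p - a
  if (abs(d) < degeneracy_tol) {
    # limits of the quotient forms as R1P -> k + R1S
    dk_21 <- TR * g11 * (1 - k * TR / 2)
    ds_21 <- -k * TR^2 * g11 / 2
    dp_21 <- -k * TR^2 * g11 / 2
  } else {
    q <- (g11 - g22) / d
    dk_21 <- q - k * TR * g11 / d + k * q / d
    ds_21 <- k * (-TR * g11 / d + q / d)
    dp_21 <- k * (TR * g22 / d - q / d)
  }
  m <- function(d11, d21, d22) matrix(c(d11, d21, 0, d22), 2, 2,
                                      dimnames = list(c("S", "P"), c("S", "P")))
  list(k = m(-TR * g11, dk_21, 0),
       R1S = m(-TR * g11, ds_21, 0),
       R1P = m(0, dp_21, -TR * g22))
}

#' Analytic signal sensitivities
#'
#' Computes the derivatives of every signal value with respect to each model
#' parameter by forward recursion alongside the state: the state sensitivity
#' is propagated with the product rule through the excitation loss and the
#' transition matrix, and the signal sensitivity follows from the sine of the
#' effective angle (plus an explicit excitation term for the B1 scale
#' parameter). Sensitivities are divided by the `normalization` factor so
#' they refer to the same scale as normalized data; the factor is treated as
#' a fixed calibration constant by default. Setting
#' `differentiate_normalization = TRUE` additionally differentiates a
#' model-based factor `S0 * sin(B1S * alpha_0)` with respect to `S0` (and
#' `B1S`), for the alternative reading in which normalization is part of the
#' model.
#'
#' @param params A [kin_params()] object.
#' @param scheme A [flip_scheme()].
#' @param variant `"without-b1s"` (5 parameters) or `"with-b1s"` (6,
#'   including the flip-angle scale).
#' @param normalization Scalar divisor applied to signals and sensitivities.
#' @param differentiate_normalization Differentiate through the
#'   normalization factor (see Details).
#' @return A list of class `sensitivity_set`: `dy`, a (2(N+1)) x p matrix in
#'   the column-major order of the 2 x (N+1) signal matrix; `dx`, the state
#'   sensitivities (not normalized); `order`, the parameter names.
#' @export
sensitivities <- function(params, scheme,
                          variant = c("without-b1s", "with-b1s"),
                          normalization = 1,
                          differentiate_normalization = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "kin_params"), inherits(scheme, "flip_scheme"),
            normalization > 0)
  with_b1 <- variant == "with-b1s"
  res <- cpp_sensitivities(theta_vector(params), deg2rad(scheme$angles),
                           scheme$TR, b1_scale(params), with_b1)
  dy <- res / normalization
  if (differentiate_normalization) {
    # d(y/C)/dtheta = dy/C - y * dC/dtheta / C^2 with C = S0 sin(B1S a0)
    sim <- cpp_simulate(theta_vector(params), deg2rad(scheme$angles),
                        scheme$TR, b1_scale(params))
    yv <- as.vector(sim$y)
    a0 <- deg2rad(scheme$angles[1]); b1 <- b1_scale(params)
    C <- params$S0 * sin(b1 * a0)
    dC_dS0 <- sin(b1 * a0)
    dy[, 4] <- dy[, 4] - yv * dC_dS0 / C^2
    if (with_b1) {
      dC_dB1 <- params$S0 * a0 * cos(b1 * a0)
      dy[, 6] <- dy[, 6] - yv * dC_dB1 / C^2
    }
  }
  colnames(dy) <- param_names(variant)
  structure(list(dy = dy, dx = state_sensitivities(params, scheme, with_b1),
                 order = param_names(variant), normalization = normalization),
            class = "sensitivity_set")
}

# State sensitivities dx/dtheta_i (2 x N+1 x p), unnormalized: the plain-R
# companion recursion to the compiled signal-sensitivity path.
state_sensitivities <- function(params, scheme, with_b1) {
  p <- if (with_b1) 6L else 5L
  nt <- length(scheme$angles)
  G <- transition_matrix(params, scheme$TR)
  dG <- transition_matrix_grad(params, scheme$TR)
  b1 <- b1_scale(params)
  al <- deg2rad(scheme$angles)
  dx <- array(0, dim = c(2L, nt, p),
              dimnames = list(c("substrate", "product"), NULL,
                              param_names(if (with_b1) "with-b1s" else "without-b1s")))
  dx[1, 1, 4] <- 1  # d/dS0
  dx[2, 1, 5] <- 1  # d/dP0
  x <- c(params$S0, params$P0)
  for (t in seq_len(nt - 1L)) {
    cs <- cos(b1 * al[t])
    for (i in seq_len(p)) {
      dxc <- cs * dx[, t, i]
      if (with_b1 && i == 6L) dxc <- dxc - al[t] * sin(b1 * al[t]) * x
      extra <- if (i <= 3L) dG[[i]] %*% (cs * x) else 0
      dx[, t + 1L, i] <- G %*% dxc + extra
    }
    x <- as.vector(G %*% (cs * x))
  }
  dx
}

#' Fisher information matrix of the dynamic experiment
#'
#' For the Gaussian measurement model, the information about the kinetic
#' parameters carried by all signal values is the sum over metabolites and
#' time points of outer products of signal sensitivities scaled by the
#' inverse noise variance. `sigma` is interpreted on the scale of the
#' normalized signals, i.e. of `y / normalization`: pass the divisor actually
#' applied to the data together with the noise level on that scale. When the
#' noise is normalized by the same divisor as the signal the two factors
#' cancel, so `normalization = 1` with a raw-scale `sigma` gives the
#' identical matrix.
#'
#' @inheritParams sensitivities
#' @param sigma Noise standard deviation per metabolite (length 1 or 2), on
#'   the scale of the normalized signals.
#' @param scale `"physical"` reports information about the physical
#'   parameters; `"nondimensional"` rescales rates by `TR` and
#'   magnetizations by the t = 0 substrate signal, so that inverse-square
#'   weights become squared relative uncertainties.
#' @param normalization Scalar divisor applied to the model signal before
#'   comparison with `sigma` (the dataset's `$normalization` in the standard
#'   pipeline).
#' @return An object of class `fim_result`: `matrix` (p x p, symmetric),
#'   `order`, `condition` (2-norm condition number), `invertible`
#'   (condition below `1e12`), plus the context (`params`, `TR`, `scale`,
#'   `y0`) needed by [crlb()] and [l_optimality()].
#' @export
fim <- function(params, scheme, sigma,
                variant = c("without-b1s", "with-b1s"),
                scale = c("physical", "nondimensional"),
                normalization = 1) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  sigma <- check_sigma(sigma)
  with_b1 <- variant == "with-b1s"
  I <- cpp_fim(theta_vector(params), deg2rad(scheme$angles), scheme$TR,
               b1_scale(params), with_b1, sigma, normalization)
  nms <- param_names(variant)
  y0 <- params$S0 * sin(deg2rad(scheme$angles[1]) * b1_scale(params))
  if (scale == "nondimensional") {
    cs <- nondim_scales(params, scheme$TR, y0, variant)
    I <- I / outer(cs, cs)
  }
  dimnames(I) <- list(nms, nms)
  sv <- svd(I, nu = 0, nv = 0)$d
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  structure(list(matrix = I, order = nms, condition = cond,
                 invertible = is.finite(cond) && cond < 1e12,
                 params = params, TR = scheme$TR, scale = scale, y0 = y0,
                 sigma = sigma),
            class = "fim_result")
}

# multiplicative scales c_i with theta_nd = c_i * theta_i
nondim_scales <- function(params, TR, y0, variant) {
  cs <- c(TR, TR, TR, 1 / y0, 1 / y0)
  if (variant == "with-b1s") cs <- c(cs, 1)
  cs
}

#' @export
print.fim_result <- function(x, ...) {
  cat(sprintf("Fisher information (%s, %s scale): %d parameters\n",
              paste(x$order, collapse = ", "), x$scale, length(x$order)))
  cat(sprintf("  condition number %.3g; invertible: %s\n",
              x$condition, x$invertible))
  invisible(x)
}

#' Cramér-Rao covariance lower bound
#'
#' Inverts the Fisher information matrix; the diagonal entries are lower
#' bounds on the variances of unbiased estimators of the corresponding
#' parameters, on the scale (`physical` or `nondimensional`) the information
#' matrix was computed on.
#'
#' @param fim_result A [fim()] result with `invertible = TRUE`.
#' @return A p x p covariance bound matrix.
#' @export
crlb <- function(fim_result) {
  stopifnot(inherits(fim_result, "fim_result"))
  if (!fim_result$invertible) {
    stop("singular information matrix (condition number ",
         format(fim_result$condition, digits = 3),
         "): Cramér-Rao bound undefined")
  }
  solve(fim_result$matrix)
}

#' L-optimality criterion
#'
#' The weighted trace `tr(W * FIM^-1)` with diagonal weights `W`: a scalar
#' summary of the Cramér-Rao bound that prioritizes selected parameter
#' variances. A-optimality is the special case of unit weights. The
#' information matrix is expected on the non-dimensional scale when the
#' conventional inverse-square weights are used, so each term is a squared
#' relative uncertainty.
#'
#' @param fim_result A [fim()] result.
#' @param weights A [weight_spec()] (entries beyond the FIM's parameters must
#'   be absent or zero).
#' @return A nonnegative scalar.
#' @export
l_optimality <- function(fim_result, weights) {
  stopifnot(inherits(fim_result, "fim_result"))
  w <- align_weights(weights, fim_result$order)
  if (all(w == 0)) return(0)
  sum(w * diag(crlb(fim_result)))
}

align_weights <- function(weights, order) {
  stopifnot(inherits(weights, "weight_spec"))
  extra <- setdiff(names(weights)[weights > 0], order)
  if (length(extra)) {
    stop("weights on parameters absent from this model variant: ",
         paste(extra, collapse = ", "))
  }
  w <- setNames(numeric(length(order)), order)
  common <- intersect(names(weights), order)
  w[common] <- weights[common]
  w
}

#' Non-dimensionalize a parameter set
#'
#' Rescales the parameters to dimensionless form: rates are multiplied by the
#' repetition time and magnetizations divided by the t = 0 substrate signal
#' (the natural time and signal units of the experiment). The returned record
#' inverts the scaling so estimates can be reported in physical units.
#'
#' @param params A [kin_params()] object.
#' @param TR Repetition time, seconds.
#' @param y0 Signal unit; defaults to `S0` (the t = 0 substrate magnetization
#'   up to the first-pulse sine, which cancels in relative quantities).
#' @return A list with `theta` (named dimensionless vector), `scales` and
#'   `TR`; invert with [redimensionalize()].
#' @export
nondimensionalize <- function(params, TR, y0 = NULL) {
  stopifnot(inherits(params, "kin_params"), TR > 0)
  y0 <- y0 %||% params$S0
  variant <- if (is.null(params$B1S)) "without-b1s" else "with-b1s"
  cs <- nondim_scales(params, TR, y0, variant)
  th <- theta_vector(params)
  if (variant == "with-b1s") th <- c(th, params$B1S)
  names(cs) <- param_names(variant)
  list(theta = setNames(th * cs, param_names(variant)), scales = cs, TR = TR)
}

#' Restore physical units after non-dimensionalization
#'
#' @param scaled The list returned by [nondimensionalize()] (possibly with an
#'   updated `theta`, e.g. after optimization on the dimensionless scale).
#' @return A [kin_params()] object in physical units.
#' @export
redimensionalize <- function(scaled) {
  th <- scaled$theta / scaled$scales
  kin_params(k = th[["k"]], R1S = th[["R1S"]], R1P = th[["R1P"]],
             S0 = th[["S0"]], P0 = th[["P0"]],
             B1S = if ("B1S" %in% names(th)) th[["B1S"]] else NULL)
}

#' Export a Fisher information or covariance matrix as CSV
#'
#' Writes the matrix with a header row naming the parameters.
#'
#' @param m A square matrix with parameter dimnames (e.g. `fim()$matrix` or a
#'   [crlb()] result).
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  df <- data.frame(parameter = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
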
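# L-optimal design of flip-angle schemes: B1 prior, regularization,
# marginalized objective, bounded multistart optimization of CFA and VFA
# schedules, Ernst angle, joint TR-and-angle CFA optimization.

#' Discretized prior over the B1 transmit-field scale
#'
#' An equidistant grid of B1S support points weighted by a normal density and
#' normalized to unit mass, used to marginalize the design objective over
#' plausible flip-angle miscalibrations. A single support point (`n_points =
#' 1`) is a delta prior and reproduces the fixed-B1 design path exactly.
#'
#' @param n_points Number of grid points (default 11).
#' @param interval Support interval (default `c(0.5, 1.5)`).
#' @param mean,sd Parameters of the weighting normal density (defaults 1 and
#'   0.15, a realistic transmit-field spread for MR experiments).
#' @return An object of class `b1_prior` with `grid` and `weights`.
#' @export
make_b1_prior <- function(n_points = 11L, interval = c(0.5, 1.5), mean = 1,
                          sd = 0.15) {
  stopifnot(n_points >= 1L, sd > 0)
  if (n_points == 1L) {
    grid <- mean
    weights <- 1
  } else {
    stopifnot(interval[1] < interval[2])
    grid <- seq(interval[1], interval[2], length.out = n_points)
    weights <- dnorm(grid, mean, sd)
    weights <- weights / sum(weights)
  }
  structure(list(grid = grid, weights = weights), class = "b1_prior")
}

#' Delta prior fixing the B1 scale
#'
#' @param value The assumed B1S value (default 1).
#' @return A single-point `b1_prior`.
#' @export
b1_delta_prior <- function(value = 1) make_b1_prior(1L, mean = value)

#' @export
print.b1_prior <- function(x, ...) {
  cat(sprintf("B1 prior: %d support points on [%g, %g]\n", length(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Design configuration
#'
#' Collects the tunable settings of the scheme optimizers.
#'
#' @param lambda Regularization strength trading off L-optimality against the
#'   sparsity-promoting excitation penalty (default 0.1, weakly informative).
#' @param sigma Design noise standard deviation (default 5e-3); it scales the
#'   objective without moving its optimum.
#' @param maxit Maximum optimizer iterations (default 10000).
#' @param fd_step Finite-difference step for objective gradients, degrees
#'   (default 1e-4).
#' @param factr L-BFGS-B relative-tolerance factor (default 1e4; each start
#'   is polished close to its local optimum so the multistart plateau is
#'   sharply resolved).
#' @param lmm L-BFGS-B memory: number of curvature pairs retained (default
#'   17; the late-pulse plateau of variable schemes needs a rich Hessian
#'   approximation to converge fully).
#' @param n_starts Number of random multistart initializations for VFA
#'   optimization (default 25).
#' @param init_range Range (degrees) of the uniform random initial angles
#'   (default `c(10, 80)`).
#' @param lower_first Lower bound for the first angle, degrees (default 0.1;
#'   keeps the normalization point excited).
#' @param penalty Objective value charged for a singular information matrix;
#'   `NULL` (default) lets the optimizers use 1e6 times the best feasible
#'   initialization value.
#' @return A list of class `design_config`.
#' @export
design_config <- function(lambda = 0.1, sigma = 5e-3, maxit = 10000L,
                          fd_step = 1e-4, factr = 1e4, lmm = 17L, n_starts = 25L,
                          init_range = c(10, 80), lower_first = 0.1,
                          penalty = NULL) {
  stopifnot(lambda >= 0, sigma > 0, n_starts >= 1L)
  structure(list(lambda = lambda, sigma = sigma, maxit = as.integer(maxit),
                 fd_step = fd_step, factr = factr, lmm = as.integer(lmm),
                 n_starts = as.integer(n_starts), init_range = init_range,
                 lower_first = lower_first, penalty = penalty),
            class = "design_config")
}

#' Sparsity-promoting excitation penalty
#'
#' The regularization term `n * sigma^2 * lambda * sum(sin(alpha)^2)` added
#' to the design objective. It weakly discourages excitations that extract
#' magnetization without contributing information, which stabilizes the tail
#' of optimized variable schemes where the gradient of the information
#' objective vanishes.
#'
#' @param angles_deg Flip angles in degrees.
#' @param lambda Regularization strength.
#' @param n Number of strictly positive parameter weights in the design.
#' @param sigma Design noise standard deviation.
#' @return A nonnegative scalar.
#' @export
regularization <- function(angles_deg, lambda, n, sigma) {
  stopifnot(n >= 1)
  n * sigma^2 * lambda * sum(sin(deg2rad(angles_deg))^2)
}

#' Prior-marginalized regularized design objective
#'
#' The expected L-optimality of a flip-angle scheme under the B1 prior: for
#' each prior support point the Fisher information of the five kinetic
#' parameters is evaluated at the effectively delivered angles `B1S * alpha`,
#' inverted, weighted, and averaged with the prior masses; the excitation
#' penalty of [regularization()] is added. A singular information matrix at
#' any support point contributes a large finite penalty so that line searches
#' can back away from degenerate schemes.
#'
#' @param angles_deg Prescribed flip angles, degrees.
#' @param params Nominal [kin_params()].
#' @param weights A [weight_spec()] on the non-dimensionalized parameters.
#' @param prior A [make_b1_prior()] object.
#' @param config A [design_config()].
#' @param TR Repetition time, seconds.
#' @param lambda Regularization strength; defaults to `config$lambda`, pass 0
#'   for the unregularized value.
#' @return The scalar objective value.
#' @export
design_objective <- function(angles_deg, params, weights, prior, config =
                               design_config(), TR = 2,
                             lambda = config$lambda) {
  stopifnot(inherits(prior, "b1_prior"))
  w <- align_weights(weights, param_names("without-b1s"))
  penalty <- config$penalty %||% 1e6
  cpp_design_objective(deg2rad(angles_deg), theta_vector(params), w,
                       prior$grid, prior$weights, TR, config$sigma, lambda,
                       n_weighted(weights), penalty)
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Optimized %s scheme: %d excitations, TR = %g s\n",
              toupper(x$mode), length(x$scheme$angles), x$scheme$TR))
  cat(sprintf("  objective %.6g (unregularized %.6g)\n", x$objective,
              x$objective_unregularized))
  cat(sprintf("  %d/%d starts converged; %d within 1%% of the best\n",
              sum(x$starts$converged), nrow(x$starts), x$best_within_1pct))
  if (x$mode == "cfa") cat(sprintf("  constant angle %.4f deg\n", x$angle))
  invisible(x)
}

design_result <- function(mode, scheme, objective, objective_unreg, starts,
                          angle = NULL, TRopt = NULL) {
  conv <- starts$converged & is.finite(starts$value_unreg)
  best <- if (any(conv)) min(starts$value_unreg[conv]) else NA_real_
  structure(list(mode = mode, scheme = scheme, objective = objective,
                 objective_unregularized = objective_unreg, starts = starts,
                 best_within_1pct =
                   sum(conv & starts$value_unreg <= best * 1.01),
                 angle = angle, TR = TRopt),
            class = "design_result")
}

#' Optimize a constant flip-angle scheme
#'
#' Minimizes the prior-marginalized L-optimality of a constant-angle scheme
#' over the single angle by bounded quasi-Newton descent from a grid of
#' initializations (10, 20, ..., 80 degrees). No regularization is applied:
#' for a constant scheme the penalty would only bias the angle. Starts that
#' fail to converge or meet a singular information matrix are recorded as
#' outliers; the best converged start is returned.
#'
#' @inheritParams design_objective
#' @param n_angles Number of excitations (default 91, t = 0..180 s at
#'   TR = 2 s).
#' @param inits Initial angles, degrees.
#' @return A `design_result`; `$angle` holds the optimized constant angle.
#' @export
optimize_cfa <- function(params, weights, prior, config = design_config(),
                         n_angles = 91L, TR = 2,
                         inits = seq(10, 80, by = 10)) {
  objf <- function(a, pen) {
    design_objective(rep(a, n_angles), params, weights, prior,
                     config_with_penalty(config, pen), TR, lambda = 0)
  }
  init_vals <- vapply(inits, objf, numeric(1), pen = 1e6)
  if (all(init_vals >= 1e6)) stop("optimization failure: no feasible CFA initialization")
  penalty <- config$penalty %||% (1e6 * min(init_vals))
  starts <- data.frame(init = inits, value = NA_real_, angle = NA_real_,
                       converged = FALSE)
  for (i in seq_along(inits)) {
    res <- optim(inits[i], function(a) objf(a, penalty),
                 method = "L-BFGS-B", lower = config$lower_first, upper = 90,
                 control = list(maxit = config$maxit, factr = config$factr,
                                lmm = config$lmm, ndeps = config$fd_step))
    starts$value[i] <- res$value
    starts$angle[i] <- res$par
    starts$converged[i] <- res$convergence == 0 && res$value < penalty
  }
  if (!any(starts$converged)) stop("optimization failure: no CFA start converged")
  starts$value_unreg <- starts$value
  best <- which(starts$converged)[which.min(starts$value[starts$converged])]
  angle <- starts$angle[best]
  design_result("cfa", cfa_scheme(angle, n_angles, TR), starts$value[best],
                starts$value[best], starts, angle = angle)
}

config_with_penalty <- function(config, penalty) {
  config$penalty <- penalty
  config
}

#' Optimize a variable flip-angle scheme
#'
#' Jointly optimizes all flip angles of the scheme by bounded quasi-Newton
#' descent (L-BFGS-B with forward-difference gradients) of the regularized,
#' prior-marginalized L-optimality objective, from `config$n_starts` random
#' initializations drawn uniformly on `config$init_range`. The first angle is
#' bounded below by `config$lower_first` so the normalization point stays
#' excited; all other angles may reach 0. Per-start records (initialization
#' seed, final value, convergence) are kept and the best converged start is
#' reported.
#'
#' @inheritParams optimize_cfa
#' @param seed Integer seed for the multistart draws; start `i` uses
#'   `seed + i - 1`, making every start individually reproducible.
#' @return A `design_result`.
#' @export
optimize_vfa <- function(params, weights, prior, config = design_config(),
                         n_angles = 91L, TR = 2, seed = 1L) {
  w <- align_weights(weights, param_names("without-b1s"))
  nw <- n_weighted(weights)
  theta <- theta_vector(params)
  h_rad <- deg2rad(config$fd_step)
  lower <- c(config$lower_first, rep(0, n_angles - 1L))
  upper <- rep(90, n_angles)

  make_init <- function(i) {
    draw_init <- function() runif(n_angles, config$init_range[1],
                                  config$init_range[2])
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed) + i - 1L)
    draw_init()
  }
  inits <- lapply(seq_len(config$n_starts), make_init)

  objf <- function(a_deg, pen, lambda) {
    cpp_design_objective(deg2rad(a_deg), theta, w, prior$grid, prior$weights,
                         TR, config$sigma, lambda, nw, pen)
  }
  init_vals <- vapply(inits, objf, numeric(1), pen = 1e6,
                      lambda = config$lambda)
  if (all(init_vals >= 1e6)) stop("optimization failure: no feasible VFA initialization")
  penalty <- config$penalty %||% (1e6 * min(init_vals))

  gradf <- function(a_deg) {
    g <- cpp_design_gradient(deg2rad(a_deg), theta, w, prior$grid,
                             prior$weights, TR, config$sigma, config$lambda,
                             nw, penalty, h_rad)
    g * pi / 180
  }

  starts <- data.frame(start = seq_len(config$n_starts), value = NA_real_,
                       value_unreg = NA_real_, converged = FALSE)
  schemes <- vector("list", config$n_starts)
  for (i in seq_len(config$n_starts)) {
    res <- optim(inits[[i]], function(a) objf(a, penalty, config$lambda),
                 gr = gradf, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = config$maxit, factr = config$factr,
                                lmm = config$lmm))
    starts$value[i] <- res$value
    starts$value_unreg[i] <- objf(res$par, penalty, 0)
    starts$converged[i] <- res$convergence == 0 && res$value < penalty
    schemes[[i]] <- pmin(pmax(res$par, lower), upper)  # L-BFGS-B roundoff
  }
  if (!any(starts$converged)) stop("optimization failure: no VFA start converged")
  conv <- which(starts$converged)
  best <- conv[which.min(starts$value[conv])]  # ties: lowest start index
  design_result("vfa", flip_scheme(schemes[[best]], TR), starts$value[best],
                starts$value_unreg[best], starts)
}

#' Ernst angle
#'
#' The constant flip angle `acos(exp(-TR * R1))` that maximizes steady-state
#' signal efficiency for repeated excitation of a species relaxing at rate
#' `R1` with repetition time `TR`.
#'
#' @param TR Repetition time, seconds.
#' @param R1 Longitudinal relaxation rate, 1/s.
#' @return The Ernst angle in degrees.
#' @examples
#' ernst_angle(2, 1/54)  # ~15.5 deg
#' @export
ernst_angle <- function(TR, R1) {
  stopifnot(TR > 0, R1 > 0)
  acos(exp(-TR * R1)) * 180 / pi
}

#' Jointly optimize repetition time and constant flip angle
#'
#' Optimizes a constant-angle scheme over both TR and the angle within a
#' fixed total acquisition window: for each candidate TR the scheme has
#' `floor(window / TR) + 1` excitations and the angle is optimized by golden
#' section plus quasi-Newton polish; the TR grid is then refined around the
#' best candidate. Used to quantify how much a TR-and-angle-optimized
#' constant scheme still trails an optimized variable scheme.
#'
#' Because the non-dimensionalization that renders the weights unit-free
#' uses the repetition time as the time unit, weights defined at one TR are
#' rescaled to each candidate TR (`w * (tr_ref / TR)^2` on the rate entries)
#' so that schemes with different TR are compared on a common physical
#' scale.
#'
#' @inheritParams design_objective
#' @param window Total acquisition duration in seconds.
#' @param TR_range Candidate TR interval, seconds.
#' @param TR_step Coarse TR grid step, seconds (also the refinement scale).
#' @param tr_ref The TR at which `weights` were defined (default 2 s).
#' @return A list with `TR`, `angle` (degrees), `objective`, `n_angles` and
#'   the optimized `scheme`.
#' @export
optimize_cfa_tr <- function(params, weights, prior, window = 150,
                            config = design_config(), TR_range = c(0.5, 40),
                            TR_step = 0.25, tr_ref = 2) {
  stopifnot(window > 0)
  best_angle_for <- function(TR) {
    n_ang <- as.integer(floor(window / TR)) + 1L
    w_tr <- weights
    rates <- intersect(names(w_tr), c("k", "R1S", "R1P"))
    w_tr[rates] <- w_tr[rates] * (tr_ref / TR)^2
    objf <- function(a) design_objective(rep(a, n_ang), params, w_tr,
                                         prior, config, TR, lambda = 0)
    o <- optimize(objf, c(config$lower_first, 90), tol = 1e-4)
    res <- optim(o$minimum, objf, method = "L-BFGS-B",
                 lower = config$lower_first, upper = 90,
                 control = list(factr = config$factr, lmm = config$lmm,
                                ndeps = config$fd_step))
    list(angle = res$par, value = res$value, n_angles = n_ang)
  }
  evaluate_grid <- function(TRs) {
    fits <- lapply(TRs, best_angle_for)
    vals <- vapply(fits, `[[`, numeric(1), "value")
    list(TR = TRs[which.min(vals)], fit = fits[[which.min(vals)]])
  }
  coarse <- evaluate_grid(seq(TR_range[1], TR_range[2], by = TR_step))
  lo <- max(TR_range[1], coarse$TR - TR_step)
  hi <- min(TR_range[2], coarse$TR + TR_step)
  fine <- evaluate_grid(seq(lo, hi, by = TR_step / 5))
  fit <- fine$fit
  list(TR = fine$TR, angle = fit$angle, objective = fit$value,
       n_angles = fit$n_angles,
       scheme = cfa_scheme(fit$angle, fit$n_angles, fine$TR))
}
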
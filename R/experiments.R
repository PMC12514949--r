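# Monte Carlo validation harnesses: estimate distributions per scheme,
# robustness to parameter mis-specification, B1 variation and recovery,
# semi-synthetic noise studies, Bland-Altman agreement, fixture generation.

#' Summarize replicate estimates
#' @noRd
mc_summary <- function(estimates, truth, n_excluded, seed, variant,
                       scheme_id = NA_character_) {
  nms <- colnames(estimates)
  truth_v <- truth[nms]
  n <- nrow(estimates)
  mean_v <- colMeans(estimates)
  sd_v <- apply(estimates, 2, sd)
  bias_v <- mean_v - truth_v
  rmse_v <- sqrt(colMeans((estimates - rep(truth_v, each = n))^2))
  structure(list(estimates = estimates, truth = truth_v, mean = mean_v,
                 sd = sd_v, bias = bias_v, rmse = rmse_v, n_reps = n,
                 n_excluded = n_excluded, seed = seed, variant = variant,
                 scheme_id = scheme_id),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary (%s%s): %d replicates, %d excluded\n",
              x$variant,
              if (!is.na(x$scheme_id)) paste0(", scheme ", x$scheme_id) else "",
              x$n_reps, x$n_excluded))
  tab <- rbind(truth = x$truth, mean = x$mean, sd = x$sd, bias = x$bias,
               rmse = x$rmse)
  print(signif(tab, 4))
  invisible(x)
}

truth_vector <- function(params, variant) {
  th <- setNames(theta_vector(params), param_names("without-b1s"))
  if (variant == "with-b1s") th <- c(th, B1S = b1_scale(params))
  th
}

fit_replicates <- function(make_dataset, scheme, variant, n_reps, truth,
                           seed, scheme_id = NA_character_) {
  nms <- param_names(variant)
  est <- matrix(NA_real_, n_reps, length(nms), dimnames = list(NULL, nms))
  ok <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    ds <- make_dataset(r)
    f <- fit_kinetics(ds, scheme, variant)
    ok[r] <- f$converged
    th <- theta_vector(f$estimates)
    if (variant == "with-b1s") th <- c(th, f$estimates$B1S)
    est[r, ] <- th
  }
  out <- mc_summary(est[ok, , drop = FALSE], truth, sum(!ok), seed, variant,
                    scheme_id)
  attr(out, "kept") <- which(ok)
  out
}

#' Monte Carlo distribution of parameter estimates under a scheme
#'
#' Simulates the noiseless experiment, normalizes it, adds `n_reps`
#' independent Gaussian noise realizations, and fits the kinetic model to
#' each, summarizing the resulting estimate distributions. A pre-drawn
#' standard-normal `noise` cube (2 x N+1 x n_reps) may be supplied so that
#' the identical realizations are reused across schemes of equal length
#' (common random numbers), which sharpens scheme comparisons.
#'
#' @param scheme A [flip_scheme()].
#' @param params Ground-truth [kin_params()].
#' @param sigma Noise standard deviation on the raw signal scale (the scale
#'   of the simulated trajectory); see `noise_on`.
#' @param n_reps Number of replicates (>= 2).
#' @param variant Fit variant, `"without-b1s"` or `"with-b1s"`.
#' @param seed Integer seed for the noise draws (ignored when `noise` is
#'   given).
#' @param noise Optional standard-normal array `dim = c(2, N+1, n_reps)`.
#' @param noise_on `"raw"` (default) adds the noise before normalization, so
#'   the noise level is identical across schemes in physical signal units
#'   and the subsequent normalization rescales data and sigma together;
#'   `"normalized"` adds `sigma` directly on the normalized scale, which
#'   couples the effective noise to the scheme's first excitation.
#' @param scheme_id Optional label carried into the summary.
#' @return An `mc_summary` with per-parameter mean, sd, bias and RMSE over
#'   converged replicates, the replicate estimates, and the exclusion count.
#' @export
mc_distribution <- function(scheme, params, sigma = 5e-3, n_reps = 1000L,
                            variant = c("without-b1s", "with-b1s"),
                            seed = 1L, noise = NULL,
                            noise_on = c("raw", "normalized"),
                            scheme_id = NA_character_) {
  variant <- match.arg(variant)
  noise_on <- match.arg(noise_on)
  stopifnot(n_reps >= 2L)
  nt <- length(scheme$angles)
  noise <- noise %||% draw_standard_noise(nt, n_reps, seed)
  stopifnot(dim(noise)[2] == nt, dim(noise)[3] >= n_reps)
  traj <- simulate_trajectory(params, scheme)
  make_dataset <- if (noise_on == "raw") {
    function(r) normalize_signals(add_noise(traj, sigma, noise = noise[, , r]),
                                  mode = "s0-sina0")
  } else {
    base <- normalize_signals(traj, mode = "s0-sina0")
    function(r) add_noise(base, sigma, noise = noise[, , r])
  }
  fit_replicates(make_dataset, scheme, variant, n_reps,
                 truth_vector(params, variant), seed, scheme_id)
}

#' Robustness of schemes to ground-truth parameter variation
#'
#' Repeats the Monte Carlo recovery study while varying one generating
#' parameter at a time over a multiplier grid (default 50%--150% of
#' nominal), fitting the model without B1S, and reports the log10 RMSE of
#' the conversion-rate estimate relative to a reference scheme. The same
#' noise realizations are used for every scheme, parameter and multiplier.
#'
#' @param schemes Named list of [flip_scheme()] objects, all of equal length.
#' @param params Nominal [kin_params()].
#' @param sigma,n_reps,seed As in [mc_distribution()].
#' @param vary Names of parameters to vary.
#' @param multipliers Multiplier grid applied to one parameter at a time.
#' @param reference Name of the reference scheme for differencing.
#' @return A data frame of class `sweep_result` with columns `scheme`,
#'   `parameter`, `multiplier`, `rmse_k`, `log10_rmse_k` and
#'   `dlog10_rmse_k` (value minus reference), plus the per-cell summaries in
#'   `attr(, "summaries")`.
#' @export
mc_robustness_sweep <- function(schemes, params, sigma = 5e-3,
                                n_reps = 1000L, seed = 1L,
                                vary = c("k", "R1S", "R1P", "S0", "P0"),
                                multipliers = c(0.5, 0.75, 1, 1.25, 1.5),
                                reference = names(schemes)[1]) {
  stopifnot(length(schemes) >= 2L, reference %in% names(schemes))
  nt <- unique(vapply(schemes, function(s) length(s$angles), integer(1)))
  stopifnot(length(nt) == 1L)
  noise <- draw_standard_noise(nt, n_reps, seed)
  cells <- expand.grid(parameter = vary, multiplier = multipliers,
                       scheme = names(schemes), stringsAsFactors = FALSE)
  summaries <- vector("list", nrow(cells))
  rmse_k <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    pert <- params
    pert[[cells$parameter[i]]] <- pert[[cells$parameter[i]]] * cells$multiplier[i]
    s <- mc_distribution(schemes[[cells$scheme[i]]], pert, sigma, n_reps,
                         "without-b1s", seed, noise,
                         scheme_id = cells$scheme[i])
    summaries[[i]] <- s
    rmse_k[i] <- s$rmse[["k"]]
  }
  cells$rmse_k <- rmse_k
  cells$log10_rmse_k <- log10(rmse_k)
  ref <- cells[cells$scheme == reference, c("parameter", "multiplier",
                                            "log10_rmse_k")]
  names(ref)[3] <- "ref_log10"
  cells <- merge(cells, ref, by = c("parameter", "multiplier"), sort = FALSE)
  cells$dlog10_rmse_k <- cells$log10_rmse_k - cells$ref_log10
  cells$ref_log10 <- NULL
  attr(cells, "summaries") <- summaries
  attr(cells, "reference") <- reference
  class(cells) <- c("sweep_result", class(cells))
  cells
}

#' Monte Carlo study with varying B1 transmit scale
#'
#' Draws a ground-truth `B1S` per replicate from a (truncated) normal
#' distribution, simulates the experiment with the correspondingly scaled
#' delivered angles, adds noise, and fits each requested model variant. For
#' fits including B1S the Pearson correlation between fitted and drawn B1S
#' is reported.
#'
#' @inheritParams mc_distribution
#' @param b1_mean,b1_sd Mean and sd of the B1S draw (defaults 1 and 0.15).
#'   `b1_sd = 0` fixes B1S at `b1_mean`.
#' @param b1_range Truncation interval for the draws; the default (0.3, 2)
#'   keeps fits inside the bounds and essentially never triggers.
#' @param fit_variants Character vector of variants to fit.
#' @return A list with one `mc_summary` per variant, the drawn `b1_true`,
#'   and `b1_correlation` (named by variant, `NA` for fits without B1S).
#' @export
mc_b1_variation <- function(scheme, params, b1_mean = 1, b1_sd = 0.15,
                            sigma = 5e-3, n_reps = 1000L,
                            fit_variants = "with-b1s", seed = 1L,
                            b1_range = c(0.3, 2), noise = NULL) {
  stopifnot(n_reps >= 2L)
  nt <- length(scheme$angles)
  noise <- noise %||% draw_standard_noise(nt, n_reps, seed)
  b1_true <- draw_truncated_b1(n_reps, b1_mean, b1_sd, b1_range,
                               seed = seed + 10000L)
  datasets <- lapply(seq_len(n_reps), function(r) {
    p_r <- params
    p_r$B1S <- b1_true[r]
    traj <- simulate_trajectory(p_r, scheme)
    normalize_signals(add_noise(traj, sigma, noise = noise[, , r]),
                      mode = "s0-sina0")
  })
  out <- list(b1_true = b1_true)
  out$b1_correlation <- setNames(rep(NA_real_, length(fit_variants)),
                                 fit_variants)
  for (v in fit_variants) {
    truth <- truth_vector(params, v)
    if (v == "with-b1s") truth["B1S"] <- b1_mean  # per-replicate truth varies
    s <- fit_replicates(function(r) datasets[[r]], scheme, v, n_reps, truth,
                        seed)
    if (v == "with-b1s") {
      drawn <- b1_true[attr(s, "kept")]
      out$b1_correlation[v] <- if (sd(drawn) > 0) {
        cor(s$estimates[, "B1S"], drawn)
      } else {
        NA_real_  # degenerate draw (b1_sd = 0): correlation undefined
      }
    }
    out[[v]] <- s
  }
  out
}

draw_truncated_b1 <- function(n, mean, sd, range, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= range[1] | x >= range[2])) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Semi-synthetic Monte Carlo study on a fixed backbone
#'
#' Treats a fixed normalized dataset -- a measured dynamic series or any
#' simulated fixture -- as the noiseless backbone and adds `n_reps`
#' independent Gaussian noise realizations, fitting the model to each. This
#' emulates repeating an experiment whose deterministic content is fixed,
#' isolating the effect of measurement noise. Because the backbone is
#' normalized by its first substrate measure (proportional to
#' `sin(alpha_0)`), applying one nominal `sigma` to schemes with different
#' first angles would correspond to different physical noise levels; with
#' `noise_scale = "sina0"` the sd is divided by `sin(alpha_0)` so the added
#' noise is comparable across schemes in physical units. `"none"` applies
#' `sigma` as given.
#'
#' @param dataset An `hp_dataset` backbone (normalized).
#' @param scheme The acquisition [flip_scheme()] (defaults to the dataset's).
#' @param sigma Base noise standard deviation.
#' @param n_reps,variant,seed As in [mc_distribution()].
#' @param noise_scale `"sina0"` or `"none"`.
#' @param truth Optional [kin_params()] for bias/RMSE reference; defaults to
#'   the dataset's generating parameters, else the noiseless fit.
#' @return An `mc_summary`.
#' @export
semisynthetic <- function(dataset, scheme = dataset$scheme, sigma = 5e-3,
                          n_reps = 1000L,
                          variant = c("without-b1s", "with-b1s"), seed = 1L,
                          noise_scale = c("sina0", "none"), truth = NULL,
                          noise = NULL) {
  variant <- match.arg(variant)
  noise_scale <- match.arg(noise_scale)
  stopifnot(inherits(dataset, "hp_dataset"), n_reps >= 2L)
  nt <- ncol(dataset$signals)
  noise <- noise %||% draw_standard_noise(nt, n_reps, seed)
  sig_eff <- if (noise_scale == "sina0") {
    sigma / sin(deg2rad(scheme$angles[1]))
  } else {
    sigma
  }
  if (!is.finite(sig_eff) || sig_eff <= 0) {
    stop("degenerate effective noise sd: first angle is 0 degrees")
  }
  truth <- truth %||% dataset$params %||%
    fit_kinetics(dataset, scheme, variant)$estimates
  make_dataset <- function(r) add_noise(dataset, sig_eff, noise = noise[, , r])
  fit_replicates(make_dataset, scheme, variant, n_reps,
                 truth_vector(truth, variant), seed)
}

#' Bland-Altman agreement between paired estimate vectors
#'
#' @param estimates_a,estimates_b Equal-length paired vectors (e.g. the same
#'   replicates fitted under two schemes with shared noise).
#' @return A list with `bias` (mean difference a - b), `limits` (bias +/-
#'   1.96 sd of differences), `sd_diff` and `n`.
#' @export
bland_altman <- function(estimates_a, estimates_b) {
  if (length(estimates_a) != length(estimates_b)) {
    stop("paired estimate vectors must have equal length")
  }
  d <- estimates_a - estimates_b
  s <- if (length(d) > 1L) sd(d) else 0
  list(bias = mean(d), limits = mean(d) + c(-1.96, 1.96) * s, sd_diff = s,
       n = length(d))
}

#' Generate a reproducible fixture suite
#'
#' Writes, for each supplied scheme: the noiseless normalized trajectory, one
#' seeded noisy dataset at the given sigma; plus a dataset generated with
#' `B1S = 0.85` under the first variable scheme (or the first scheme), and a
#' model-mismatch backbone in which the conversion rate decays linearly by
#' 5% over the record. All files are plain CSV with provenance headers;
#' identical inputs and seed give byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param schemes Named list of [flip_scheme()] objects.
#' @param params Generating [kin_params()] (default [nominal_params()]).
#' @param sigma Noise sd for the noisy datasets.
#' @param seed Integer seed.
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixtures <- function(dir, schemes, params = nominal_params(),
                              sigma = 5e-3, seed = 1L) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  stopifnot(length(schemes) >= 1L, !is.null(names(schemes)))
  paths <- character(0)
  for (nm in names(schemes)) {
    sc <- schemes[[nm]]
    traj <- normalize_signals(simulate_trajectory(params, sc))
    p1 <- file.path(dir, paste0(nm, "_noiseless.csv"))
    write_dataset(as_dataset(traj, sigma), p1, seed = seed)
    noisy <- add_noise(traj, sigma,
                       noise = draw_standard_noise(length(sc$angles), 1L,
                                                   seed)[, , 1])
    p2 <- file.path(dir, paste0(nm, "_noisy.csv"))
    write_dataset(noisy, p2, seed = seed)
    paths <- c(paths, p1, p2)
  }
  # B1-miscalibrated dataset (synthetic stand-in for a miscalibrated coil)
  first_vfa <- names(schemes)[vapply(schemes, function(s)
    length(unique(s$angles)) > 1L, logical(1))]
  b1_nm <- if (length(first_vfa)) first_vfa[1] else names(schemes)[1]
  p085 <- params
  p085$B1S <- 0.85
  traj_b1 <- normalize_signals(simulate_trajectory(p085, schemes[[b1_nm]]))
  p3 <- file.path(dir, paste0(b1_nm, "_b1_085.csv"))
  write_dataset(as_dataset(traj_b1, sigma), p3, seed = seed)
  # model-mismatch backbone: k decays linearly by 5% over the record
  sc <- schemes[[b1_nm]]
  p4 <- file.path(dir, paste0(b1_nm, "_mismatch.csv"))
  write_dataset(as_dataset(mismatch_trajectory(params, sc), sigma), p4,
                seed = seed)
  invisible(c(paths, p3, p4))
}

# trajectory with a slowly drifting conversion rate (stepwise-constant k),
# used as a deliberate model-mismatch backbone
mismatch_trajectory <- function(params, scheme, drift = 0.05) {
  nt <- length(scheme$angles)
  b1 <- b1_scale(params)
  al <- deg2rad(scheme$angles)
  x <- matrix(0, 2, nt)
  y <- matrix(0, 2, nt)
  xv <- c(params$S0, params$P0)
  for (t in seq_len(nt)) {
    x[, t] <- xv
    y[, t] <- sin(b1 * al[t]) * xv
    p_t <- params
    p_t$k <- params$k * (1 - drift * (t - 1) / max(nt - 1, 1))
    G <- transition_matrix(p_t, scheme$TR)
    xv <- as.vector(G %*% (cos(b1 * al[t]) * xv))
  }
  traj <- structure(list(x = x, y = y, scheme = scheme, params = NULL,
                         normalization = 1),
                    class = "hp_trajectory")
  traj$y <- traj$y / y[1, 1]
  traj$x <- traj$x / y[1, 1]
  traj$normalization <- y[1, 1]
  traj
}
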
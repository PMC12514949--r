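---
title: "Optimal flip-angle design and kinetic model fitting for hyperpolarized MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal flip-angle design and kinetic model fitting for hyperpolarized MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfadesign)
```

## The model

Hyperpolarized substrates carry a non-renewable magnetization budget: it
decays by longitudinal relaxation and is consumed by every radio-frequency
excitation. `vfadesign` models a two-metabolite unidirectional conversion
(substrate S to product P, e.g. ethyl acetoacetate to acetoacetate under
carboxyl esterase, or pyruvate to lactate) as a hybrid discrete-time system.
Between excitations the longitudinal magnetization $x = (x_S, x_P)^\top$
evolves by

$$\frac{dx}{dt} = \begin{pmatrix} -(k + R_{1S}) & 0 \\ k & -R_{1P} \end{pmatrix} x,$$

where $k$ is the apparent first-order conversion rate and $R_{1S} = 1/T_{1S}$,
$R_{1P} = 1/T_{1P}$ the relaxation rates. Over one repetition time $TR$ this
integrates to the lower-triangular transition matrix $G = \exp(TR \cdot A)$,
implemented in closed form with a series limit at the degeneracy
$R_{1P} = k + R_{1S}$ (`transition_matrix()`; threshold $10^{-8}$ 1/s on the
rate difference, below which the quotient form loses digits to
cancellation).

An excitation with prescribed flip angle $\alpha_t$ converts
$\sin(B_{1S}\alpha_t)\,x_t$ into measurable transverse signal $y_t$ and
leaves $\cos(B_{1S}\alpha_t)\,x_t$ behind. The dimensionless scale $B_{1S}$
maps prescribed to actually delivered angles and represents transmit-field
miscalibration; the model "without $B_{1S}$" pins it at 1. Measured signals
are the noiseless $y$ plus i.i.d. Gaussian noise, equal for both metabolites.

Assumptions worth keeping in mind: conversion is unidirectional and
first-order with constant $k$; both metabolites are excited by the same
broadband pulse; pulses are instantaneous; transverse magnetization is fully
spoiled between excitations; noise is Gaussian and homoscedastic (magnitude
data near the noise floor, where Rician corrections matter, are out of
scope).

## Information, bounds and the design objective

For the Gaussian data model the Fisher information about
$\theta = (k, R_{1S}, R_{1P}, S_0, P_0[, B_{1S}])$ is the sum over
metabolites and excitations of outer products of the signal sensitivities
$\partial y_{m,t}/\partial\theta_i$ divided by the noise variance (`fim()`).
Sensitivities are computed analytically by a forward product-rule recursion
alongside the state (`sensitivities()`), and the whole forward path is
implemented in compiled code; finite differences of the simulated signal
serve as an independent oracle in the test suite. The inverse information
is the Cramér–Rao lower bound on the estimator covariance (`crlb()`).

Designs are scored by L-optimality, $\mathrm{tr}(W\,\mathcal{I}^{-1})$ with
diagonal weights $W$ (`l_optimality()`). Parameters are first
non-dimensionalized — rates multiplied by $TR$, magnetizations divided by
the first substrate signal — so that the conventional weights
$1/\theta_{nd}^2$ turn each term into a squared relative uncertainty
(`design_weights()`). Because the time unit is $TR$ itself, weighted
objectives at different $TR$ are not directly comparable; the joint
TR-and-angle optimizer (`optimize_cfa_tr()`) therefore rescales the weights
to a fixed reference $TR$ before comparing candidates. The noise level
scales the objective without moving its optimum, so the design is
noise-level-free; the package still carries $\sigma$ through so that
bound and Monte Carlo scatter can be compared on one scale.

Robustness to transmit miscalibration enters by marginalizing the objective
over a discretized $B_{1S}$ prior (`make_b1_prior()`): 11 equidistant
support points on $[0.5, 1.5]$ weighted by a normal density with mean 1 and
sd 0.15 (a realistic transmit spread), normalized to unit mass. We
normalize the density weights; unnormalized weights would only rescale the
objective without moving the optimum. A single-point prior
(`b1_delta_prior()`) recovers the fixed-$B_1$ design path exactly, which is
the configuration used for stable NMR setups.

A sparsity-promoting penalty $n\sigma^2\lambda\sum_t \sin^2\alpha_t$
(`regularization()`, $\lambda = 0.1$) is added during variable-scheme
optimization. Late excitations act on depleted magnetization, so the
information objective has essentially no gradient there; the penalty pulls
those angles to zero instead of leaving them at their random
initialization, making converged schemes comparable across starts. It is
deliberately weak: the unregularized objective of the $\lambda = 0.1$
optimum agrees with the $\lambda = 0$ optimum to well under 1%.

## Optimizers

Constant schemes are optimized over the single angle from the
initialization grid 10°, 20°, ..., 80° and without regularization (which
would merely bias a constant angle); variable schemes optimize all angles
jointly from 25 random initializations drawn uniformly on [10°, 80°]
(per-start seeds `seed + i - 1`, so every start is individually
reproducible). Both use bounded quasi-Newton descent (L-BFGS-B) with
forward-difference gradients (step $10^{-4}$ degrees) computed in compiled
code; angles are bounded to [0°, 90°], with a 0.1° lower bound on the
first angle so the normalization point stays excited. A singular
information matrix (condition number above $10^{12}$) is charged a large
finite penalty — $10^6$ times the best feasible initialization value — so
line searches can back away from degenerate schemes rather than aborting;
such starts are recorded as outliers. Ties between equal-objective starts
go to the lowest start index.

## The acquisition horizon

The package's default scheme is 91 excitations at $TR = 2$ s, i.e.
$t = 0..180$ s. The optimal constant angle falls slowly with the horizon,
since more excitations share the same magnetization budget; at 180 s the
optimum sits at 13.5° under the B1 prior and 13.4° with fixed $B_1$ (the
values the acceptance checks recompute), consistent with the terminal 90°
pulses of optimized variable schemes landing near 125 s. All functions take
the scheme length as an argument.

## Noise conventions

Dynamic series are conventionally normalized by their first substrate
measure before analysis. The package treats that divisor as a fixed
calibration constant: the model for normalized data is the unnormalized
model divided by the stored factor, and sensitivities are divided by the
same constant (an optional flag differentiates through a model-based factor
instead, for the alternative reading in which normalization is part of the
model; the information matrix is unaffected either way because the factor
cancels between signal and noise).

In the Monte Carlo harness, noise of sd $5\times10^{-3}$ is added on the
raw signal scale — identical physical noise for every scheme — and data and
sd are then normalized together (`mc_distribution(noise_on = "raw")`).
Adding equal noise on the *normalized* scale instead couples the effective
noise to the scheme's first flip angle (a scheme whose first pulse is large
is normalized by a large divisor, shrinking its normalized noise), which
inverts scheme comparisons; that convention remains available as
`noise_on = "normalized"`. For the semi-synthetic harness, whose backbone
is already normalized, the same reasoning leads to dividing the nominal sd
by $\sin\alpha_0$ so that added noise is comparable across schemes in
physical units.

The same 1000 standard-normal draws are reused across schemes (common
random numbers, shared by time index), which removes most of the Monte
Carlo noise from scheme-to-scheme ratios of estimate scatter.

## Fitting

`fit_kinetics()` minimizes the sum of squared residuals on included points
(excitations with a 0° prescribed angle are excluded — they carry no
signal) by bounded Levenberg–Marquardt with the analytic residual Jacobian.
Under the homoscedastic Gaussian model this is maximum likelihood. Bounds
are generous physical ranges: $k \in [0, 1]$ 1/s, rates in $[10^{-3}, 1]$
1/s, magnetizations in $(0, 100]$, $B_{1S} \in [0.3, 2]$. Starting values
come from the data (`initial_guess()`): first-point magnetizations, typical
relaxation rates, and an early-slope estimate of $k$ clipped to
$[10^{-4}, 1]$. Non-converged fits are retried from three deterministically
perturbed starts (no RNG is consumed, preserving bit-reproducibility of
seeded studies) and flagged, never silently accepted; Monte Carlo summaries
exclude and count them.

The $B_{1S}$-aware variant is refused for constant-angle schemes: with one
common angle the scale is completely correlated with $S_0$, $P_0$ and the
relaxation rates and cannot be identified. Monte Carlo draws of $B_{1S}$
are truncated to $(0.3, 2)$ to stay inside the fit bounds; an untruncated
$N(1, 0.15)$ essentially never leaves that range.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions: nominal parameters
$k = 0.0135$ 1/s, $T_{1S} = 35$ s, $T_{1P} = 54$ s, $S_0 = 5$, $P_0 = 0.1$
(a mis-specified variant multiplies all rates by 1.5), Gaussian noise of sd
$5\times10^{-3}$, and transmit scales drawn from $N(1, 0.15)$. It does not
emulate spectral processing (phasing, baseline, peak integration), Rician
magnitude statistics, arterial input functions, back-conversion, or
temperature-driven drift of $k$ — except for a dedicated model-mismatch
fixture whose conversion rate decays linearly by 5% over the record, used
to check that mild mismatch shifts estimates without breaking the
machinery. Passing tests therefore demonstrate correctness of the
estimation and design machinery under the stated model, not robustness to
every artifact of real spectra.

## Problem sizes and numerical settings

The test suite and the acceptance script optimize schemes of 91 excitations
with 25 multistarts, run 1000-replicate recovery studies at $\sigma =
5\times10^{-3}$, and use a TR grid of 0.25 s (refined 5-fold) for the joint
TR/angle search over a 180 s window — the same horizon as the variable
schemes, so both arms of that comparison observe the system for equally
long. Near-optimal variable schemes form a plateau: typically 14–18 of 25
starts land within 1% of the best objective, and members of that plateau
can differ by a few percent in their fixed-$B_1$ bound on $k$, which is the
dominant source of run-to-run variation in the reported scatter
reductions.

## Limitations

Single unidirectional conversion only; no transverse dynamics,
off-resonance or slice profiles; equal flip angles for both metabolites
(no spectrally selective excitation); the design assumes the nominal
parameters are roughly right — the robustness sweep quantifies, but does
not remove, the cost of optimizing around wrong nominals.
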
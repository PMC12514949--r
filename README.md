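# vfadesign

Optimal flip-angle design and kinetic parameter estimation for dynamic
hyperpolarized magnetic resonance experiments.

Hyperpolarized substrates (e.g. [1,3-13C]ethyl acetoacetate, or
[1-13C]pyruvate in vivo) carry a non-renewable magnetization budget that is
consumed by relaxation and by every excitation pulse. How that budget is
spent — the schedule of flip angles over the acquisition — determines how
precisely the kinetic parameters of the metabolic conversion can be
estimated afterwards. `vfadesign` is for experimenters and methodologists
who want excitation schedules that minimize the uncertainty of those
estimates, and who need the companion fitting and validation machinery.

## The model and the criterion

Longitudinal magnetization `x = (x_S, x_P)` of substrate and product evolves
between excitations by the two-compartment kinetic generator

    dx/dt = [ -(k + R1S)   0    ] x
            [      k     -R1P   ]

discretized over one repetition time as `G = expm(TR * A)`. An excitation at
prescribed angle `alpha_t` yields signal `sin(B1S * alpha_t) * x_t` and
leaves `cos(B1S * alpha_t) * x_t`, where `B1S` is the transmit-field scale
(1 when the coil is perfectly calibrated). From the analytic signal
sensitivities the package builds the Fisher information matrix `I(theta;
alpha)` and scores a design by L-optimality, `tr(W * I^-1)`, with
inverse-square weights on non-dimensionalized parameters so each term is a
squared relative uncertainty. Robustness to transmit miscalibration comes
from marginalizing the objective over a discretized `B1S` prior (11 points
on [0.5, 1.5], normal weights N(1, 0.15)):

    min_alpha  sum_g p_g * tr(W * I(theta; B1S_g * alpha)^-1)  +  n sigma^2 lambda sum_t sin^2(alpha_t)

The last term weakly promotes sparsity of late, uninformative pulses
(lambda = 0.1). Constant (CFA) and variable (VFA) schedules are optimized by
bounded multistart L-BFGS-B; model fitting is bounded Levenberg-Marquardt
with analytic Jacobians, with or without `B1S` as a free parameter; Monte
Carlo harnesses validate designs by parameter recovery under common random
numbers.

## Worked example

```r
library(vfadesign)

params <- nominal_params()      # k = 0.0135 /s, T1S = 35 s, T1P = 54 s, S0 = 5, P0 = 0.1
prior  <- make_b1_prior()       # 11-point N(1, 0.15) prior on [0.5, 1.5]

# constant angle optimized for the conversion rate k
cfa <- optimize_cfa(params, design_weights(params), prior)
cfa$angle
#> [1] 13.52369

ernst_angle(TR = 2, R1 = 1/54)  # product Ernst angle, the classical heuristic
#> [1] 15.49786

# variable schedule optimized for k (25 random starts, seeded)
vfa <- optimize_vfa(params, design_weights(params), prior,
                    design_config(n_starts = 25), seed = 7)
round(vfa$scheme$angles[vfa$scheme$angles > 1], 1)
#> [1] 32.1 29.1 36.6 31.4  9.4 64.4 90.0

# how much better is the variable schedule? Monte Carlo recovery, shared noise
noise <- vfadesign:::draw_standard_noise(91, 400, seed = 11)
m_cfa <- mc_distribution(cfa$scheme, params, sigma = 5e-3, n_reps = 400, noise = noise)
m_vfa <- mc_distribution(vfa$scheme, params, sigma = 5e-3, n_reps = 400, noise = noise)
100 * (1 - m_vfa$sd[["k"]] / m_cfa$sd[["k"]])
#> [1] 29.96394
```

The optimized constant angle (13.5 deg) sits just below the product Ernst
angle (15.5 deg). The optimized variable schedule concentrates excitation in
an initial pulse, a cluster near t = 25 s and large terminal pulses past
100 s, and reduces the Monte Carlo standard deviation of the fitted
conversion rate by roughly a third relative to the best constant angle; the
square root of the Cramér-Rao bound reproduces the Monte Carlo scatter to
within a percent.

A thin command-line wrapper is installed under `inst/cli/vfadesign`:

```sh
Rscript inst/cli/vfadesign ernst --tr 2 --t1 54
#> 15.5
```

## Package layout

- `R/kinetics.R` — parameters, schemes, forward simulation, noise, normalization
- `R/fisher.R` — sensitivities, Fisher information, Cramér-Rao bound, L-optimality
- `R/design.R` — B1 prior, design objective, CFA/VFA/CFA-TR optimizers, Ernst angle
- `R/inference.R` — bounded maximum-likelihood fitting, initial guesses
- `R/experiments.R` — Monte Carlo harnesses, Bland-Altman, fixture generation
- `R/io.R`, `R/cli.R` — CSV/JSON readers and writers, command-line dispatcher
- `src/forward.cpp` — compiled forward model, sensitivity recursion, design objective
- `vignettes/design-methods.Rmd` — the model, conventions and design decisions
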
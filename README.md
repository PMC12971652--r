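# virimmune

Within-host viral infection rarely ends in a single stereotyped outcome:
depending on the host's initial immune configuration, the same exposure can
resolve quietly, lock into chronic inflammation, or leave the immune system
switched into a persistently activated state. `virimmune` implements a
six-compartment ODE model of the virus–immune feedback network and the full
dynamical-analysis pipeline needed to study that heterogeneity: stiff
scenario simulation, an equilibrium census with stability classification,
one- and two-parameter bifurcation scans, basin-of-attraction maps over
initial conditions, infectious/illness-duration indicators under parameter
perturbation, and exhaustive subsystem bistability analysis.

It is written for modellers in viral dynamics and systems immunology who
want a tested, scriptable counterpart to GUI-driven continuation and
simulation toolboxes.

## The model

Six dimensionless module intensities — viral load $V$, innate immunity $I$,
cellular immunity $C$, humoral immunity $H$, immune suppression $S$ and
IL-6 ($L$) — interact through Hill terms
$h(x;k,n) = x^n/(k^n + x^n)$:

```
dV/dt = α(t) + a_v0·h(V) − [d_v1·h(C) + d_v2·h(I) + d_v3·h(H)]·V − d_v4·V
dI/dt = a_I0·h(V) + a_I1·h(I) − d_I2·h(S)·I − d_I3·I
dC/dt = a_C0·h(I)·h(V) + a_C2·h(C) − d_C3·h(S)·C − d_C4·C
dH/dt = a_H0·h(C) + a_H1·h(I) − d_H2·h(S)·H − d_H3·H
dS/dt = δ + a_S0·h(C) + a_S1·h(I) − d_S2·h(L)·S − d_S3·S
dL/dt = a_IL0·h(C) + a_IL1·h(V) − d_IL2·L
```

each Hill term with its own half-saturation constant and coefficient (63
parameters; `default_parameters()` holds the canonical set). The exogenous
input `α(t)` is a piecewise-constant exposure: level φ on `[0, T]`, zero
after, with optional re-exposure pulses. Time is in days; states are
dimensionless module intensities.

## A worked example

```r
library(virimmune)

# 7-day low-level exposure from the canonical baseline state
sc   <- canonical_scenarios()$finite_7d        # phi = 0.01, T = 7 days
traj <- simulate_model(sc$x0, sc$params, sc$schedule, sc$cfg)

traj$times[which.max(traj$states[, "V"])]
#> [1] 7        -- the viral load peaks exactly at the input cutoff

post <- traj$states[nrow(traj$states), ]
recovery_time(traj, post, c("V", "I", "C", "IL6"), frac_tol = 0.1)
#> [1] 9.8      -- V, I, C and IL-6 are back within 10% of their post-input
#>                 steady levels ~3 days after the cutoff

# equilibrium landscape under continuous input 0.01
find_equilibria(default_parameters(), alpha_level = 0.01,
                n_starts = 200, seed = 1)
#> <equilibrium_set> 5 equilibria (3 stable) at alpha = 0.01, n_starts = 200, seed = 1
#>   [stable]   leading Re(lambda) = -7.234e-01  state = (0.01161, 0.3202, 1.233, ...)
#>   [unstable] leading Re(lambda) = +1.232e+00  state = (0.04886, 0.4749, 2.207, ...)
#>   [stable]   leading Re(lambda) = -5.765e-01  state = (2.664, 0.4975, 3.245, ...)
#>   [stable]   leading Re(lambda) = -5.328e-01  state = (0.01549, 0.3408, 0.06231, ...)
#>   [unstable] leading Re(lambda) = +9.695e-01  state = (0.01187, 0.3214, 0.2334, ...)
```

Three stable states coexist at one parameter set — a controlled low-virus
state with cellular immunity engaged, the same with cellular immunity shut
down, and a chronic high-virus state — so the outcome is decided by the
initial immune configuration.

The `analysis/` directory holds the numbered drivers that reproduce the
full study: `01_trajectories.R` (exposure scenarios and reversibility),
`02_equilibria_bifurcation.R` (census, branches, two-parameter count
scan), `03_basins.R` (initial-condition maps and outcome densities),
`04_durations.R` (duration indicators and ±30% perturbation sensitivity),
`05_subsystems.R` (the 63-subsystem bistability table). Each writes tidy
CSVs plus JSON manifests under `results/`.

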
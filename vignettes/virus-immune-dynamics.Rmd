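---
title: "A virus-immune feedback network: model, multistability, and recovery analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virus-immune feedback network: model, multistability, and recovery analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`virimmune` implements a coarse-grained within-host model of the immune
response to viral infection. Six dimensionless module intensities evolve in
time (days): viral load $V$, innate immunity $I$, cellular immunity $C$,
humoral immunity $H$, immune suppression $S$, and the pro-inflammatory
cytokine IL-6 ($L$ below). Every cross-module activation, clearance and
suppression effect is a Hill function
$$h(x; k, n) = \frac{x^n}{k^n + x^n},$$
which saturates at 1, reaches one half at $x = k$, and switches with
steepness $n$. The six equations are

$$
\begin{aligned}
\dot V &= \alpha(t) + a_{v0}\,h(V;k_{v0},n_{v0})
  - \big[d_{v1} h(C;k_{v1},n_{v1}) + d_{v2} h(I;k_{v2},n_{v2})
  + d_{v3} h(H;k_{v3},n_{v3})\big] V - d_{v4} V,\\
\dot I &= a_{I0}\,h(V) + a_{I1}\,h(I) - d_{I2}\,h(S)\,I - d_{I3} I,\\
\dot C &= a_{C0}\,h(I)\,h(V) + a_{C2}\,h(C) - d_{C3}\,h(S)\,C - d_{C4} C,\\
\dot H &= a_{H0}\,h(C) + a_{H1}\,h(I) - d_{H2}\,h(S)\,H - d_{H3} H,\\
\dot S &= \delta + a_{S0}\,h(C) + a_{S1}\,h(I) - d_{S2}\,h(L)\,S - d_{S3} S,\\
\dot L &= a_{IL0}\,h(C) + a_{IL1}\,h(V) - d_{IL2} L,
\end{aligned}
$$

with each Hill term carrying its own $(k, n)$ pair (63 parameters in all;
`default_parameters()` lists every one with its canonical value). The
exogenous input $\alpha(t)$ equals a level $\phi$ on an exposure window
$[0, T]$ and zero outside it, with optional re-exposure pulses
(`input_schedule()`). Clearance and decay terms vanish with their variable,
so the vector field never points out of the nonnegative orthant and each
variable obeys a closed-form long-run cap (e.g.
$V \le (\phi + a_{v0})/d_{v4}$); both properties are asserted in the test
suite.

Two details deserve note. The basal suppression rate $\delta$ defaults to
$2\times 10^{-4}$; a value of $10^{-4}$ also circulates for this model, and
`delta` is an ordinary overridable parameter. All canonical Hill
coefficients are 3; coefficients below 1 are rejected because the Hill
derivative would be singular at the boundary, where the Jacobian must stay
defined.

## Simulation

`simulate_model()` integrates the system with deSolve's stiff-capable
`lsoda`, supplying the analytic Jacobian. Defaults are deliberately tight
(`rel_tol` $10^{-8}$, `abs_tol` $10^{-10}$): basin classification and
branch structure are sensitive to integration error. Integration restarts
at every jump of $\alpha(t)$, so no step straddles a discontinuity. Tiny
negative undershoots — purely numerical, since the exact field is inward —
are clipped to zero and counted on the returned trajectory.

`steady_state_by_integration()` declares convergence only when the residual
max-norm of the field *and* the state variation over a trailing window
(default 10 days) both fall below `conv_tol`. The reference analysis never
defined "reaches steady state" precisely, so convergence times are
reported under this explicit rule.

A worked scenario:

```{r, eval = FALSE}
library(virimmune)
sc <- canonical_scenarios()$finite_7d      # input 0.01 for 7 days
traj <- simulate_model(sc$x0, sc$params, sc$schedule, sc$cfg)
traj$times[which.max(traj$states[, "V"])]  # viral peak: at the cutoff, t = 7
post <- traj$states[nrow(traj$states), ]
recovery_time(traj, post, c("V", "I", "C", "IL6"), frac_tol = 0.1)
# ~9.8 days: fast components settle within 10% of their post-input levels
# about 3 days after the cutoff; H and S settle slightly above their
# pre-exposure values and recover on a slower timescale
```

## Equilibria and stability

`find_equilibria()` runs a damped Newton iteration (backtracking line
search, projection onto the nonnegative orthant) from `n_starts`
log-uniform random starts over $[10^{-4}, 10]$ per variable — a box
covering both the canonical magnitudes and the near-zero branches — plus
the origin and the canonical baseline state. Roots converge to residual
$<10^{-10}$, are discarded if any component falls below $-10^{-9}$, are
clamped to zero below $10^{-12}$, and are deduplicated componentwise at
relative tolerance $10^{-6}$ (absolute floor $10^{-9}$), chosen to keep
genuinely distinct near-zero branches apart while merging numerical
duplicates. Stability follows the eigenvalues of the analytic Jacobian with
a margin: all real parts below $-10^{-7}$ is stable, any above $+10^{-7}$
unstable, otherwise marginal (forcing a binary call at $10^{-16}$ would
just amplify noise). Every census records `n_starts` and `seed`, and
saturation — no new roots under more starts and a different seed — is the
completeness check, since no multistart protocol was ever published for
this model.

At the canonical parameters under continuous input 0.01 the census finds
five equilibria, three stable: a low-virus state with cellular immunity
high, a low-virus state with cellular immunity shut down, and the chronic
high-virus state.

## Bifurcation analysis

`sweep_parameter()` traces branches by running the census on a parameter
grid and linking roots across adjacent values by nearest-neighbour matching
in state space; `two_parameter_count_scan()` maps total and stable
equilibrium counts over a log-spaced 2-D grid. This grid-census design was
chosen over pseudo-arclength continuation because the quantities of
interest are branch diagrams and counts, not continuation internals; folds
are then sharpened by bisection on the leading eigenvalue
(`refine_fold()`), and Hopf candidates — sign changes of the real part of a
complex pair — are verified by simulating past the crossing and requiring
at least three post-transient peaks with a peak-height coefficient of
variation below 5% (`detect_hopf()`). Oscillatory regimes exist in this
model only for particular parameter/initial-condition combinations that
were never published; the package therefore ships the detection capability
rather than a fixed oscillation preset, and no Hopf arises along
single-parameter sweeps from the canonical point.

Scan ranges default to two decades centred on each parameter's canonical
value (the published ranges are not stated). On the default
$(a_{v0}, d_{v1})$ grid ($15\times15$, 200 starts per node) the maximum
number of coexisting equilibria is 9, of which at most 4 are stable. The
count of five coexisting steady states is attained over a broad band. Two
findings differ from the published narrative and are worth recording:

* the *stable* count never reaches five at input 0.01, because the fifth
  candidate state (innate and cellular immunity both low at low virus)
  is destroyed by the input-driven viral floor $V \approx \phi/d_{v4}$,
  which is strong enough to re-activate innate immunity;
* the monostable region sits at large $a_{v0}$ / small $d_{v1}$ (the virus
  forces a single chronic state), not in the opposite corner: at small
  $a_{v0}$ and large $d_{v1}$ the self-activation bistabilities of $I$ and
  $C$ (e.g. $a_{C2} h(C) - d_{C4} C$ on its own) persist independently of
  the viral parameters, so three stable states remain. Counting steady
  states as visually distinct branches in a single-variable projection —
  plausibly what a continuation-based analysis reports — merges those
  states and recovers the published picture.

## Basins of attraction

Under efficient cellular clearance (`d_v1 = 100`, continuous input 0.01)
the virus is cleared from every initial condition and the long-run outcome
is decided by the immune modules. `basin_scan()` integrates each node of an
$(I_0, C_0)$ grid to steady state and classifies the outcome against
high/low thresholds on $C$ and IL-6. Thresholds are self-calibrating — the
midpoint between the lowest and highest stable-branch values found by the
census at the scenario's parameters — with manual override; grid defaults
cover $[0, 2]^2$, the magnitude range of the canonical states.

The scan finds exactly three attractors with contiguous basins: cellular
immunity high with innate immunity settled ($C \approx 1.21$), cellular
immunity high with innate immunity shut down, and cellular immunity low
with a residual input-driven viral load. Because IL-6 is produced only by
$C$ and $V$, the two high-$C$ attractors share an identical (C, IL-6)
pair once the virus is cleared, so the (C, IL-6)-threshold classification
resolves two labels — the third distinction lives in $I$. The packaged label
set marks the cleared high-$C$ outcome as an anomaly (low IL-6 with high
C); the basin CSV always carries the full final states, from which the
three-attractor structure is recovered directly. `outcome_density()`
replicates a scan under multiplicative jitter on $(I_0, C_0)$ (default
$\pm 2\%$, 50 replicates — the published randomization protocol is not
stated) and kernel-smooths per-class frequencies with a separable Gaussian
(bandwidth in grid cells); probabilities are degenerate away from basin
boundaries and strictly fractional near them. Resolving that mixing
requires grid spacing comparable to the jitter amplitude, which is why the
density examples zoom on a boundary band.

## Duration indicators

The infectious duration is the time $V$ spends at or above a threshold
$\theta_V$ from first sustained onset to first sustained offset; the
illness duration is the same functional of IL-6 against $\theta_{IL6}$
(`durations_for()`). Crossings are interpolated linearly between samples; a
debounce window (`min_duration`, default 0.1 day) suppresses numerical
blips; episodes still open at the horizon `t_end` are censored, with the
duration measured to the horizon. A threshold never reached gives duration
zero with both times absent — the subtraction defining the duration is
undefined there, and zero preserves "no infectious phase".

No numeric thresholds were published. Defaults are $\theta_V = 0.05$ and
$\theta_{IL6} = 0.02$, a few percent of the high-state peak scale; both are
echoed into every result. Note the canonical 7-day scenario peaks at
$V \approx 0.0116$, *below* the default $\theta_V$, so its default
infectious duration is 0; analyses that want a positive infectious phase in
that scenario pass an explicit lower threshold, as the worked examples do.

`sensitivity_experiment()` varies one focal parameter across orders of
magnitude while every non-focal rate parameter ($a_\cdot$, $d_\cdot$,
$\delta$) is multiplied by an independent $\mathrm{Uniform}(0.7, 1.3)$ draw
per replicate — the most literal reading of "random fluctuation within
±30%" — while half-saturation constants and Hill coefficients stay fixed.
The $k_{v0}$ sweep shows the model's sharpest nonlinearity: an abrupt
transition near $k_{v0} \approx 0.1$ between a chronic regime (censored at
the horizon) and a short-duration regime. Mechanistically the chronic side
is the *small*-$k_{v0}$ side — $k_{v0}$ appears only in the replication
denominator, so growth weakens monotonically as it rises — which reverses
the direction stated in the source narrative; the transition location and
its abruptness are as described. $d_{v3}$ (humoral clearance) acts smoothly
and $a_{I1}$ mildly, with irregular behaviour at low values.

## Subsystem analysis

`enumerate_subsystems()` builds all $2^6-1 = 63$ variable subsets; excluded
variables are clamped at the resting baseline steady state (the long-run
state from the canonical initial conditions with no input — the published
analysis says "steady-state levels" without naming which, so the clamp
source is explicit and configurable). Each subsystem is swept over one
focal parameter — $d_{v1}$ whenever $V$ is a member, otherwise the
self-activation strength of the highest-priority member ($I$: $a_{I1}$,
$C$: $a_{C2}$, $H$: $a_{H0}$, $S$: $a_{S0}$, IL-6: $a_{IL0}$); the
published choice of "one key parameter" is not stated, so the policy is
recorded in the results and overridable. A subsystem is bistable when any
focal value supports at least two stable equilibria of the reduced field
(`detect_bistability()`, reusing the multistart census restricted to the
active dimensions).

With the default policy, every subsystem containing at least one of $V$,
$I$, $C$ is bistable (the viral fold under $d_{v1}$, and the $I$ and $C$
self-activation switches), while the seven subsystems built only from
$\{H, S, IL6\}$ are not — their reduced dynamics are effectively linear in
each variable. The membership table (`membership_frequency()`) therefore
shows the core-triplet dominance: bistability fraction 1.0 for Group 1 of
$V$, $I$ and $C$ versus 0.875 for Group 1 of $H$, $S$ and IL-6.

## Problem sizes and numerical choices

The shipped analyses and tests use deliberately modest sizes, stated here
as the package's own defaults: count scans $15\times15$ with 200 starts
per node (a $41\times41$ preset exists for fine maps), basin grids
$9\times9$–$31\times31$, densities with 8–20 replicates, subsystem sweeps
with 7–13 focal values and 40–60 starts. Saturation checks (doubling
starts, changing seeds) back each size choice. All randomness flows through
explicit integer seeds; RNG state is restored after every seeded
operation.

## Known limitations

* Basin volumes are characterized only on 2-D initial-condition slices;
  no claim is made about six-dimensional basin geometry.
* Branch linking by nearest neighbour can mislabel a fold when two branches
  pass close together between grid points; refining the grid (the
  refinement invariance asserted in the tests) is the guard.
* `refine_fold()` tracks the followed root by Newton continuation; past a
  disappearance fold Newton may land on a different branch, in which case
  the reported bracket is conservative and flagged `root_lost`.
* The scenario generator emulates parameter sets, input schedules and
  initial-condition ensembles only; it does not emulate measurement noise,
  inter-individual parameter correlation, or any physical-unit
  calibration, all deliberately out of scope for a dimensionless model.
  Passing tests therefore certify the dynamical analysis, not agreement
  with clinical data.
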
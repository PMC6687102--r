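---
title: "Directed migration in spatial ecological public goods games: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed migration in spatial ecological public goods games: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgg)
```

## The model

### Ecological public goods

Groups of up to `N` individuals play a public goods game: each cooperator
invests `c` into a common pool, the pool is multiplied by `r > 1` and
shared equally among the group's members. Facing `n_C` cooperating
co-players in a full group, a defector earns `n_C r c / N` and a
cooperator the same minus the net cost `(1 - r/N) c` — the social dilemma
whenever `r < N`.

The ecological variant couples these payoffs to demography. Densities of
cooperators `u` and defectors `v` live on the simplex `u, v >= 0`,
`u + v <= 1`, and `w = 1 - u - v` is the density of empty space —
reproductive opportunity. Birth happens at rate `w (b + f)`, death at
constant rate `d`:

$$\partial_t u = u\,[w(b + f_C) - d], \qquad
  \partial_t v = v\,[w(b + f_D) - d].$$

The mean payoffs `f_C`, `f_D` average the game over groups whose `N - 1`
co-player slots are filled independently: cooperator with probability
`u`, defector with `v`, empty with `w`. Writing `x = u/(u+v)` for the
cooperator fraction among occupied slots, the averages have closed forms

$$f_D = r c\, x \left[1 - \frac{1 - w^N}{N (1 - w)}\right], \qquad
  f_C = f_D - c\left[1 + (r - 1) w^{N-1}
        - \frac{r}{N}\,\frac{1 - w^N}{1 - w}\right].$$

These are exactly the expectations of the per-group rule "each of the
`S` occupied members receives `r c n_C / S`, cooperators pay `c`, and a
cooperator with no co-players abstains (payoff 0)"; the test suite
verifies this equivalence against direct multinomial group sampling. Two
removable singularities are evaluated analytically: `(1 - w^N)/(1 - w)`
is computed as the geometric sum $\sum_{k=0}^{N-1} w^k$ (finite at
`w = 1`), and `x` is guarded at `u + v = 0` (no co-players, `f_D = 0`).
At `w = 0` the difference `f_C - f_D` collapses to the classic
`-c (1 - r/N)`.

### Equilibrium and Hopf bifurcation

Because `f_C - f_D = -c G(w)` depends on the state only through `w`, the
interior equilibrium `Q` reduces to a 1-D root problem: solve
`G(w_eq) = 0` on `(0, 1)` (the root `w = 1` is always present and
excluded), then the growth condition `w(b + f_D) = d` fixes the
cooperator fraction
`x_eq = (d/w_eq - b) / (r c h(w_eq))` with `h(w) = 1 - \sum w^k / N`.
`Q` is interior only if `x_eq` lands in `(0, 1)`; otherwise
`interior_equilibrium()` returns `NULL` ("absent"), which is distinct
from a root-search failure (an error). The bracketing scan uses 4001
points on `(0, 1)` and each root is polished by four Newton iterations,
so a homogeneous field initialized at `Q` is a fixed point of the
discrete integrator to ~1e-15 per step. In the regime studied here
(`d > b`, harsh environment) exactly one interior root occurs; if
several ever exist the densest one is returned.

The interaction Jacobian `J_I` at `Q` uses analytic payoff derivatives
(validated against central finite differences at relative 1e-4).
`find_hopf()` bisects on the sign of the maximal real part of the
eigenvalues of `J_I` in `r` to `|Δr| <= 1e-4`; with `b = 1, d = 1.2,
N = 8, c = 1` this lands at

```{r hopf}
find_hopf(epgg_game(b = 1, r = 2.4, c = 1, d = 1.2, N = 8))
```

Below this value the well-mixed coexistence equilibrium is unstable and
trajectories spiral to extinction; above it cooperators and defectors
coexist. This reproduction is the acceptance gate for the payoff closed
forms: if it moved, the payoff reconstruction would be wrong.

### Space and directed migration

On a periodic `L × L` domain the densities become fields and migration
enters in two forms — diffusion, and taxis along density gradients:

$$\partial_t u = u[w(b+f_C)-d] + D_C \nabla^2 u
  - A_C \nabla\!\cdot\!(u w \nabla u) + R_C \nabla\!\cdot\!(u w \nabla v),$$
$$\partial_t v = v[w(b+f_D)-d] + D_D \nabla^2 v
  - A_D \nabla\!\cdot\!(v w \nabla u) + R_D \nabla\!\cdot\!(v w \nabla v).$$

A term `-K ∇·(φ w ∇ψ)` moves type `φ` up the gradient of type `ψ` at
rate `K`, throttled by the local empty space `w`. The four modes:
cooperator aggregation (`A_C`), defector hunting (`A_D`), cooperator
flight (`R_C`, sign flipped: down the defector gradient) and defector
spreading (`R_D`, defectors avoid each other). Cooperator density is the
proxy for public goods availability; defector density the proxy for
exploitation.

### Linear stability and pattern onset

Perturbing the homogeneous state at `Q` with a diagonal plane wave
`exp(ik(x+y))` applied to both fields (the two strategies' patterns are
strongly correlated, so a common mode is imposed) linearizes the system
to `J_I + k^2 J_S`, with

$$J_S = 2\begin{pmatrix} A_C u_{eq} w_{eq} - D_C & -R_C u_{eq} w_{eq}\\
  A_D v_{eq} w_{eq} & -R_D v_{eq} w_{eq} - D_D \end{pmatrix}.$$

The dispersion relation `λ(k)` is the largest eigenvalue real part;
`λ(k) > 0` marks unstable modes. Three derived criteria:

- **Well-posedness.** `λ(k) < 0` as `k → ∞` requires
  `D_C > A_C u_eq w_eq`: diffusion must beat aggregation at the
  equilibrium, else arbitrarily fine perturbations grow and the
  continuum model breaks down (the strong-aggregation,
  discontinuity-forming regime).
- **Necessary condition.** For a linearly stable `Q`, a spatial band can
  only open if the activation terms (cooperator aggregation, slow `D_C`)
  outweigh the inhibition terms (defector hunting, cooperator flight,
  `D_D`), evaluated with the computed Jacobian entries — the sign
  pattern of the off-diagonal entries is not assumed. This is exactly
  the condition for the `k^2`-coefficient of `det(J_I + k^2 J_S)` to be
  negative; since `tr(J_S) < 0` in the well-posed regime, trace-driven
  (oscillatory) instability at `k > 0` is impossible, which is why the
  condition is genuinely necessary there.
- **Dominant mode.** `k*` is the argmax of `λ` over the unstable band,
  refined by quadratic interpolation through the grid maximum (checked
  against golden-section optimization to 1e-3 relative in the tests).

The automatic `k`-grid spans `[0, k_max]` with ~400 points mixing linear
and geometric spacing, `k_max` chosen so the quadratic decay dominates
the `k = 0` scale; if a well-posed curve is still positive at the edge
the grid is extended geometrically until it comes back below zero.

A note on wavelengths: the ansatz `exp(ik(x+y))` has physical wavevector
`(k, k)`, magnitude `k√2`. Whether a measured pattern should be compared
to `k*` or `k*√2` is therefore ambiguous a priori;
`pattern_wavelength()` reports both conversions. In practice the
radially averaged spectra of simulated smooth patterns peak at
`q* ≈ k*√2` (e.g. `q* = 0.785` vs `k*√2 = 0.787` for spreading
defectors at `r = 2.4`, `D_D = 0.5`, `R_D = 2`), consistent with the
diagonal reading.

## Numerics

### Discretization

Fields live on `n = L/dx` nodes per side at `x_i = i·dx` (node-centred;
this places a node exactly at the domain centre `L/2`, where the
reference Gaussian initial condition attains its printed amplitude 1/5),
periodic in both axes. The reference discretization is `dx = 0.375`,
`dt = 0.01`, forward Euler; a two-stage Heun mode exists for refinement
studies. The diffusive stability guard
`dt <= 0.9 dx² / (4(max(D_C, D_D) + taxis surcharge))` is a warning, not
an error, so printed reproduction protocols are honoured as given.

The Laplacian is the standard 5-point stencil. Taxis terms use a
conservative flux form: the face flux between neighbouring nodes is the
arithmetic face mean of `φw` times the face gradient of `ψ`; divergence
is the net face flux over `dx`. Both operators telescope over the
periodic grid, so migration conserves total mass to machine precision —
only the reaction term changes it (asserted every step in the tests).
An upwind (donor-cell) face average is available as a robustness
fallback for the steep-gradient aggregation regime; central is
second-order (observed order ≥ 1.9 in manufactured-solution tests) and
is the default for smooth patterns.

After each step densities are projected back onto the simplex: negatives
clipped to zero, cells with `u + v > 1` rescaled. The projected mass is
logged per step; a run whose cumulative clipped mass exceeds 1e-3 of the
domain mass is flagged. Non-finite values abort with the offending cell
and time. Runs whose domain-mean density stays below 1e-5 for 100
consecutive steps exit early as extinct.

All randomness lives in the initial condition (`initial_state()` with an
integer seed; the global RNG state is saved and restored), so a
simulation is bit-reproducible given its seed.

### Steepening and regimes

Strong cooperator aggregation feeds back positively on itself — steeper
cooperator gradients attract more cooperators — and the well-posedness
margin only bounds the linear regime. The integrator therefore monitors
the dimensionless jump per cell `max|∇u|·dx`; above 0.2 the run is
flagged as steepening, and such results are reported as
discretization-dependent rather than converged. `classify_regime()`
turns the diagnostics into one of five labels (extinct, homogeneous,
smooth_pattern, discontinuous, localized_no_expansion) via a fixed
decision tree with exposed thresholds: extinction first, then
homogeneity (late-time `var(u+v) < 1e-6`), then arrested expansion
(front-radius growth below 5e-3 while the 99%-mass radius has not filled
0.4·L — the strong-aggregation signature), then the steepening flag,
else smooth pattern.

### Reduced-scale protocol

Desk-scale analyses use `L = 24` (64 nodes per side) rather than the
reference `L = 75`, which holds 2–3 wavelengths of the dominant patterns
(`2π/q* ≈ 8`). Two protocol choices follow from the smaller domain:

- The localized (Gaussian) initial blob is scaled with the domain, width
  5 instead of 16. A width-16 blob on `L = 24` is nearly homogeneous, so
  low-`r` runs die of the well-mixed instability before spatial
  structure can rescue them — a domain-size artifact, not a model
  property.
- Pattern-versus-equilibrium ratios
  `r_p = (ū + v̄)/(u_eq + v_eq)` and
  `r_c = [ū/(ū + v̄)]/[u_eq/(u_eq + v_eq)]` are late-time (quasi-steady)
  quantities, averaged over the final 10% of the diagnostics series.
  The smooth-pattern battery (spreading defectors `R_D ∈ {2, 4, 8}` at
  `r = 2.4`, `D_C = 0.1`, `D_D = 0.5`, homogeneous start plus small
  noise) runs each case for at least seven e-folding times of its
  dominant mode (`1/λ(k*) ≈ 110, 30, 15`), i.e. `t_end = 800` for
  `R_D = 2` and 400 otherwise, so the ratios are measured on the
  saturated pattern rather than the transient.

The linear-regime validation seeds a single diagonal plane-wave mode
along the dominant eigenvector of `J_I + k² J_S` with amplitude 1e-3 and
fits the log-amplitude of its cosine projection over time; measured
growth/decay rates match `λ(k)` to well under the asserted 10% (the
residual discrepancy is the `O(k²dx²)` difference between the discrete
and continuum operators).

What the synthetic protocols do **not** emulate: demographic
stochasticity (densities are continuous fields; defector density can
become arbitrarily small but never exactly zero in finite time), finite
populations, explicit public-good concentration fields, and the
full-scale (`L = 75`, `t = 2000`) phenomenology whose snapshot content
is scheme-dependent in the discontinuous regime. Passing tests show the
deterministic PDE behaves as analysed at reduced scale; they do not by
themselves establish behaviour of discrete microbial populations.

## Parameters at a glance

| symbol | meaning | units | default |
|---|---|---|---|
| `b` | baseline birth rate | 1/time | 1 |
| `r` | pool multiplication factor | — | 2.325 |
| `c` | cost of cooperation | payoff | 1 |
| `d` | death rate | 1/time | 1.2 |
| `N` | maximal group size | count | 8 |
| `D_C`, `D_D` | diffusion | length²/time | 0.1 |
| `A_C`, `A_D`, `R_C`, `R_D` | taxis rates | length²/time per density | 0 |
| `L`, `dx`, `dt` | domain, spacing, step | length, length, time | 75, 0.375, 0.01 |

The default interaction set is the harsh-environment regime `d > b`
below the Hopf point, where survival hinges on spatial structure; the
coexistence analyses in this vignette move `r` to 2.4 (above
`r_Hopf ≈ 2.3659`).

## Known limitations

- The strong-aggregation regime (`A_C u_eq w_eq` approaching or
  exceeding `D_C`) develops discontinuities; the integrator flags
  steepening but makes no convergence claim there, and the linear
  analysis is silent beyond the necessary conditions.
- Only the common-mode (`k = l`) perturbation analysis is implemented;
  mixed-mode two-wavenumber perturbations are out of scope.
- The Hopf locator detects the crossing; it does not continue the limit
  cycles born there.
- The explicit integrator is the reference scheme; no implicit or
  operator-splitting solver is provided, so stiff parameter sets are
  bounded by the CFL-type guard.
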
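---
title: "Curriculum learning in sparse teacher-student perceptrons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curriculum learning in sparse teacher-student perceptrons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curricula)
```

## The model

A teacher perceptron `w_T` of dimension `N` has only its first
`round(ρN)` components non-zero (i.i.d. standard normal); it labels inputs by
`y = sign(w_T · x_r)`, using the *relevant* block only. Inputs are Gaussian,
`x = [x_r, x_i]`, with unit variance on the relevant block and per-sample
variance `Δ` on the irrelevant block. `Δ` is the difficulty knob: at `Δ = 0`
an example exposes the support of the teacher perfectly; at large `Δ` the
signal is hidden in clutter. A dataset is a union of slices, each slice
sharing one `Δ` and containing `α_k N` samples. Strategies order the slices:
*curriculum* (increasing `Δ`), *anti-curriculum* (decreasing), or *none*
(pooled, uniformly shuffled). Two slices with `Δ = (0, 1)` and `ρ = 0.5` are
the package-wide reference task; all constructors take arbitrary slice
lists.

The generator (`make_teacher()`, `sample_slice()`, `make_schedule()`)
emulates exactly this population model, which is what the asymptotic theory
describes. It does **not** emulate feature correlations, label noise,
heavy-tailed inputs, or continuous difficulty distributions — passing tests
therefore certify the theory/simulator agreement inside this model class,
not performance on any empirical dataset.

## Online dynamics

The student is a single-layer erf network trained online (each sample used
once) on the squared error with per-step weight decay `γ`. In the
`N → ∞` limit the macroscopic state `(Q_r, Q_i, R, T)` is self-averaging and
evolves deterministically. Averaging the one-step update over the joint
Gaussian law of the student field `λ = W·x/√N` (variance
`Q = Q_r + Δ Q_i`) and teacher field `ν` (variance `T`, covariance `R`)
gives, per step of size `1/N`:

* `R` gains `(η/N) E[G ν]` and decays by `(1 − γ)`;
* `Q_r` gains the drift `2(1 − γ)(η/N) E[G λ_r]` **and** the diffusion term
  `(η²/N) ρ E[G²]` — the latter is `O(1)` per unit `α` and cannot be
  dropped; `Q_i` analogously with weight `(1 − ρ)Δ`;
* the `O(η²)` correction to `R` is exactly zero (a single inner product),
  so nothing is discarded there.

Here `G = σ'(λ)(sign ν − σ(λ))` is the error signal. All four expectations
(`E[Gν]`, `E[Gλ_r]`, `E[Gλ_i]`, `E[G²]`) reduce to elementary closed forms
in `asin` and square roots; `E[Gλ]` is split into relevant/irrelevant parts
through the conditional mean of `λ_r` given `(λ, ν)`. The forms were derived
from Gaussian integration identities and are continuously validated against
Monte-Carlo averages of the literal SGD increment (property tests on a state
grid; the same check at `10⁷` samples is part of the acceptance suite).

**Discrete map, not an ODE.** Because `γ` acts per SGD step, its cumulative
effect depends on the step count; we therefore iterate the per-example map
`α N_theory` times (`N_theory` default `10⁴`, exposed in `online_config()`)
rather than integrating a continuous-time limit. This keeps the decay
`(1 − γ)` literal and makes the convention visible in the API.

**Shuffled baseline in expectation.** For strategy `"none"` the per-step
increment is the slice-probability mixture of the per-`Δ` increments — a
deterministic map. A stochastic mode (`baseline = "stochastic"` in
`run_theory()`) draws the per-step difficulty without replacement instead and
is used to validate the mixture map.

**Initial conditions.** Weights of variance `σ₀²` give
`Q_r(0) = ρσ₀²`, `Q_i(0) = (1 − ρ)σ₀²`, `R(0) = 0`. The default
`σ₀² = 10⁻⁴` is the small-initialisation regime in which curriculum is
typically optimal; `σ₀² = 1` reproduces the large-initialisation regime in
which anti-curriculum can win.

**Metrics.** `test_loss()` and `accuracy()` are the exact large-`N`
expressions for the mean-squared error of the erf student and the sign-match
probability; both depend on the test difficulty only through
`Q_r + Δ Q_i`. `asin` arguments are clipped at `±(1 − 10⁻¹⁵)` to absorb
rounding; arguments beyond `1 + 10⁻¹²` raise an error instead of being
silently clipped. A zero-norm student is defined to have accuracy 1/2
(random guessing), with a message.

**Teacher-norm convention.** The theory uses the self-averaging value
`T = ρ` exactly, removing an `O(1/√N)` bias; the simulators use the sampled
teacher's empirical `T`. Accuracy is invariant under rescaling of the
teacher, so the convention affects intermediate numbers, not the comparisons.

## Batch learning and the elastic coupling

Each batch phase minimises
`Σ_μ log(1 + exp(−y λ)) + (γ/2)|W|² + (γ₁₂/2)|W − W₁|²`, where `W₁` is the
previous phase's minimiser (absent in phase 1). Because the problem is
strongly convex, batch training without the coupling is *memoryless*: the
final state is determined by the last slice alone, and no curriculum effect
can survive. The elastic term is what lets earlier phases matter.

The zero-temperature replica-symmetric saddle point is solved in two
channels:

* **Energetic** (`energetic_channel()`): for each slice, the Gaussian
  expectation of the Moreau envelope of the logistic loss, with curvature
  `χ = χ_r + Δ χ_i` (the response parameters that remain finite in the
  zero-temperature limit of the norm-variance parameters) and a cavity field
  of variance `Q_r + Δ Q_i` correlated `R` with the teacher field. The inner
  proximal problem is solved by a safeguarded vectorised Newton iteration
  (bracket `[yh, yh + χ]`, bisection fallback, ulp-aware tolerance
  `10⁻¹²`).
* **Entropic** (`entropic_channel()`): the exact Gaussian integral of the
  per-coordinate quadratic measure. Sparsity enters as separate relevant and
  irrelevant blocks (fractions `ρ` and `1 − ρ`); the teacher-alignment
  conjugate acts on the relevant block only. Because the two phases see
  independent data, the anchor enters phase 2 only through its converged
  order parameters, which also yield the cross-overlaps and the typical
  anchor distance `|W₂ − W₁|²/N`.

`solve_phase()` iterates the two channels with damping 0.5 until the maximum
order-parameter change falls below `10⁻⁹` (defaults in `solver_config()`);
the damping halves automatically if the residual stagnates for 50
iterations, which handles locally expansive maps near degenerate fixed
points such as `α → 0`. The converged state also reports the predicted
training objective per dimension, which is checked against the finite-`N`
minimum in the test suite — a directly observable form of free-energy
stationarity, alongside finite-difference checks of the channel partials.

**Quadrature.** The sign label makes the energetic integrand non-smooth at
`ν = 0`, which destroys the spectral accuracy of plain Gauss–Hermite. Using
the exact `(h, y) → (−h, −y)` symmetry, the teacher field is folded onto the
positive half-line and integrated against the explicit Gaussian density with
Gauss–Legendre on `[0, 10]` (truncated mass `< 10⁻²²`), keeping
Gauss–Hermite for the orthogonal direction. The folded rule is accurate to
about `10⁻¹³` already at 21 nodes per dimension; the default is 121 nodes,
and the experiment drivers use 61 for speed at no measurable accuracy cost.
A dense Simpson/Gauss–Hermite double integration over the *unfolded* plane
serves as the independent oracle in the tests.

**Accuracy of a chained strategy** is evaluated with the same closed-form
`accuracy()` at the final phase's order parameters, on the hardest slice's
`Δ` unless configured otherwise (sign readout at test time, so the formula
is shared with the online case).

## Experiment drivers

`optimise_cell()` grid-searches hyperparameters separately per strategy and
cell, maximising final hard-instance accuracy; `phase_diagram()`,
`difficulty_scan()` and `sparsity_scan()` assemble the ratio tables. The
default grids (`default_search_online()`, `default_search_batch()`) are
log-spaced desk-scale choices: `η ∈ [10⁻², 10]` (13 points),
`γ ∈ {0} ∪ [10⁻⁶, 10⁻¹]` (12), `σ₀² ∈ {10⁻⁴, 10⁻², 1}` online;
`γ₁ = γ₂ ∈ [10⁻⁴, 10]` (15), `γ₁₂ ∈ {0} ∪ [10⁻³, 10²]` (17) batch. The
batch searches warm-start along the coupling grid. Non-convergent points are
skipped and counted; a cell is invalid only if every point fails. Default
diagram resolution is 12×12; the acceptance suite runs single-row smoke
versions.

Two qualitative facts the scans expose, worth knowing before reading a
diagram: the curriculum/baseline accuracy ratio is non-monotone in the test
difficulty with its maximum at intermediate `Δ` (roughly `Δ ≈ 8–16` at the
reference setting, so scans should extend well past `Δ = 1`); and with
point-wise optimised `(γ, γ₁₂)` the ordering curriculum ≥ anti-curriculum
holds throughout while anti-curriculum ≥ baseline holds in most but not all
cells (it fails where the easy fraction is small), so the batch ordering is
asserted as typical rather than universal.

## Problem sizes and reproducibility

The validation suite uses `N = 4000` with 10 seeds for the online
theory/simulation comparison (agreement within 0.01 in accuracy),
`N = 2000` with 10 seeds for the batch comparison, `N_theory = 5000`–`10⁴`
for theory trajectories, and 61-node quadrature in scans — sizes chosen so
the full suite runs on a laptop-class single core in minutes while leaving
the finite-size gaps an order of magnitude below the tolerances. Every
stochastic object is seeded (`make_teacher()`, `sample_slice()`, simulator
seed lists), and equal seeds give bit-identical results.

## Known limitations

* Difficulty takes finitely many levels per dataset; continuous `Δ`
  distributions are out of scope.
* The replica solver assumes the replica-symmetric ansatz, exact here
  because every phase objective is strongly convex — non-convex losses or
  architectures would require replica-symmetry breaking machinery that is
  deliberately absent.
* Online training is plain SGD (no mini-batching, momentum, or adaptive
  step sizes); batch training is full optimisation (no early stopping, by
  design — memory effects enter only through the explicit coupling).
* Phase diagrams at the default resolution are qualitative instruments;
  cell-exact values depend on the hyperparameter grids, which are package
  choices.
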
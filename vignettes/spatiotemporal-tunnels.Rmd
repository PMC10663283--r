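---
title: "Spatiotemporal tunnels in feasible muscle activation space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal tunnels in feasible muscle activation space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actspace)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why they default
where they do, what the synthetic-data generator does and does not emulate,
the numerical choices, and the known limitations.

## The model

An isometric, tendon-driven limb is summarized by one linear map: the
activation-to-wrench matrix `H` (`n_w` wrench components by `n_m` muscles),
so that a normalized activation vector `a ∈ [0,1]^{n_m}` produces the
endpoint wrench `w = H a`.  Activation 1 means 100% of a muscle's maximal
tension contribution; activations cannot be negative because muscle can
only pull.  All limb geometry (moment arms, the Jacobian) is folded into
`H`, which the package treats strictly as input data — it can be read from
a labeled CSV (`read_h_matrix()`) or generated synthetically.

*Single moment.*  The feasible activation space of one wrench is the
convex polytope `{a : H a = w, a ∈ [0,1]^{n_m}}`.  With `n_m > n_w` it is
generically a positive-volume slice of the unit cube of dimension
`n_m − rank(H)` — muscle redundancy.

*Sequence of moments.*  Muscles take time to change force.  The package
models this as a Lipschitz bound on the discrete activation path — the
activation-contraction constraint δ: `|a_{t+1,i} − a_{t,i}| ≤ δ` for every
muscle `i` and consecutive 50-ms slices `t, t+1`.  A single rate constant
is used for activation and deactivation (a deliberate simplification;
physiological deactivation is slower, so a shared fast constant is the
permissive choice).  Stacking `T` slices yields one polytope over
`n_m · T` variables: per-slice equality blocks `H a_t = w_t`, two
inequality rows per muscle and slice pair for the rate bound, and `[0,1]`
box bounds.  For the reference seven-muscle finger model over seven slices
this is the 49-variable system with 28 equality and 84 rate rows; its
equality null space has dimension 21.

*The task.*  The reference task rotates a force of fixed magnitude (10 N)
from pure palmar (`fx`) through `arc_degrees` (30°) toward proximal (`fz`)
and symmetrically back, over `n_steps = 7` slices of 50 ms.  The rotation
progress is a single cosine period peaking at the middle slice, so
`w_t = w_{T−1−t}` componentwise.  The torque row and the off-plane force
are held at zero: the task is a pure force-redirection.  The anatomical
axis convention is configuration, not anatomy-derived — the rotation plane
defaults to `fx → fz` but any pair of wrench components can be named.

## Uniform sampling

The scientific point of the sampler is neutrality: it characterizes *all*
solutions, uniformly at random, rather than the optimum of any assumed
metabolic or neural cost.  The implementation is Hit-and-Run on the
null-space chart of the polytope:

1. **Chart.**  The equality system is reduced by singular-value
   decomposition: a minimum-norm particular solution plus an orthonormal
   null-space basis (rank tolerance: largest singular value × 1e-10, with a
   warning recorded when singular values fall near the threshold).  Points
   are `x = anchor + B z`, so equalities hold identically; bounds and rate
   rows become unit-norm inequality rows in `z`.
2. **Interior point.**  The chain starts at a Chebyshev-center-style point:
   the slack-maximizing point of the chart inequalities, computed as a
   quadratic program with a small ridge (1e-7) for uniqueness.  A best
   margin below −1e-9 means the polytope is empty (classed infeasibility
   error); a margin within ±1e-9 means a zero-volume relative interior
   (classed degeneracy error, carrying the point when it is unique).
3. **Steps.**  From the current point, draw an isotropic (spherically
   symmetric) direction, intersect it with every inequality row to get the
   feasible chord, and jump to a uniform point on the chord.  Isotropic
   directions are the standard sufficient condition for a uniform
   stationary distribution on a convex body.  Rows nearly orthogonal to
   the direction (|component| < 1e-13) cannot bound the chord and are
   skipped.  Slacks are recomputed from scratch at every step, so no
   numerical drift accumulates along the chain; retained samples are
   audited against bounds/inequalities at 1e-9 and equalities at 1e-6
   before a store is returned.

Burn-in defaults to 1,000 steps and thinning to 10.  These are not claims
about mixing theory; they are validated empirically against an exact
rejection-sampling oracle (uniform proposals in an outer box of the chart,
guarded to chart dimension ≤ 4) on fixtures with closed-form geometry: the
two-muscle segment `{a₁ + a₂ = 1}`, the planar triangle, and the 3-D cube.
The uniformity suite uses fixed per-test α = 0.01 across its 6
Kolmogorov–Smirnov comparisons plus one χ² and two energy-distance tests;
with tests this numerous, occasional borderline p-values are expected and
the fixed-α policy keeps the suite stable.

Two degenerate limits are handled explicitly rather than rejected.  At
δ = 0 the rate rows are converted to equalities (all slices equal), which
keeps the relative interior well-defined; the feasible set is then the
intersection of all single-moment polytopes.  A polytope whose equalities
pin a unique point is sampled as that point, repeated, with a warning.

## The synthetic model generator

Real activation-to-wrench matrices come from cadaver or imaging
experiments and are not bundled here.  `generate_synthetic_h()` makes the
whole pipeline testable without external data: standard-normal entries,
columns scaled to unit norm, then one global scale chosen from nonnegative
cone coefficients (`H₀ λ = w_t`, nonnegative least squares) so a known
feasible activation lies in `[0, 0.5]^{n_m}` for every task wrench.  A
candidate is accepted only if every moment polytope retains an interior
margin of at least 0.01 activation units and the stacked system is
feasible at the task's δ; otherwise it is redrawn (bounded attempts).  The
generator is a pure function of its arguments, including the seed.

What this emulates is the *geometry class* of the real problem: a
redundant linear map under box bounds for which the whole task is strictly
feasible.  What it does not emulate: the anatomical correlation structure
of real moment arms, realistic wrench-unit scaling, or inter-specimen
variability.  Passing tests on synthetic models therefore demonstrate the
correctness of the constraint construction, sampler and analyses — not any
quantitative property of a particular limb.  Quantities such as the
seeded/unseeded hull ratio are model-dependent: on synthetic models the
mean next-slice ratio at δ = 0.12 typically lands in the 10–50% band,
whereas a specific cadaver-based model can be far more constrained.

## The seeded protocol

The "tunnel" analyses quantify how choosing a first activation pattern
conditions the future:

1. Sample the unseeded trajectory polytope at a condition δ.
2. Keep trajectories whose maximal absolute speed is ≤ the filter δ
   (default 0.12); draw `k = 10` of them uniformly (fixed seed) and keep
   only their `t = 0` slices — the seeds.
3. For each seed, append equality rows pinning slice 0 (and, in the
   clamped variant, the final slice) to the seed, and re-sample.
4. Fit a PCA per time slice on the *unseeded* slice data only (centered,
   unscaled); project both unseeded and seeded slices through that shared
   chart; the loading sign is fixed deterministically (dominant entry
   positive) so areas and figures are reproducible.
5. Report per-slice convex-hull areas and the seeded/unseeded ratio.

Hull areas are computed exactly (convex hull + shoelace formula) in the
PC-plane coordinates.  An alternative used in image-based workflows is
rasterizing the scatter and tracing pixels; exact geometry removes the
resolution dependence, and pixel-area arithmetic can still be reproduced
by passing scalar areas to `seeded_reduction_ratio()`.  The ratio is
invariant to rigid rotations of the PC plane and to the sign convention.

Two subtleties worth noting.  First, polytope containment (seeded ⊆
unseeded) is exact and is audited at the constraint level, but *estimated*
hulls from finite samples can overshoot slightly at later slices, where
the seeded spread approaches the unseeded one; ratios marginally above 1
at those slices are estimation noise, not a violation.  Second, the PCA is
fitted per time slice; fitting one pooled chart across slices is a
reasonable alternative reading of the protocol, but per-slice fitting
matches the per-force-direction framing and keeps each slice's projection
maximally informative.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `delta` | 0.12 (task), grid 1…0.05 | fraction of maximal activation per 50 ms | 0.12 is a generous physiological bound; the grid spans vacuous (1) to near-frozen (0.05) |
| `step_ms` | 50 | ms | activation-contraction time scale of the rate bound |
| `magnitude`, `arc_degrees` | 10 N, 30° | — | sub-maximal force, moderate redirection |
| `burn_in`, `thin` | 1000, 10 | steps | validated against the exact oracle; configurable |
| `n_seeds` | 10 | — | seeds per condition in the seeded protocol |
| seed filter | 0.12 | — | matches the headline condition; the generator checks feasibility down to the smallest grid δ |

Problem sizes are a package choice balancing statistical resolution
against desk-scale runtimes: the test suite samples hundreds of
trajectories per condition, and the acceptance script thousands (5,000
unseeded, 1,500 per seed, 2,000 per audit condition); both scales pass the
identical audits, and larger runs are a matter of configuration.

## Numerical choices

* Equality-consistency tolerance at construction: 1e-8; post-hoc sample
  audits: 1e-6 (equalities) and 1e-9 (bounds/inequalities).
* Rank tolerance for null-space extraction: max singular value × 1e-10.
* Chord rows with |directional component| < 1e-13 are skipped.
* Infeasible stacked systems are diagnosed by solving growing prefixes of
  the slice sequence and reporting the first prefix that fails — an
  actionable pointer to the wrench transition δ cannot bridge.
* Seeds must reproduce the first wrench to 1e-8 before pinning rows are
  added; bound violations and first-moment infeasibility raise distinct
  errors.
* Quartiles in occupancy summaries use linear interpolation (`type = 7`).
* Per-condition RNG seeds derive from one root seed via a 32-bit FNV-1a
  hash of `"root|delta|stage"`, so stages are reproducible independently;
  every store embeds a configuration fingerprint and cross-stage checks
  refuse mixed runs.

## Limitations

* Isometric only: wrench sequences, not movements; no joint kinematics.
* The rate bound is a box (per-muscle, per-step) constraint; it does not
  model series-elastic dynamics, muscle-type differences, or asymmetric
  activation/deactivation constants.
* Uniform sampling is the point, not a claim about neural selection; no
  cost-weighted or density-based measures are provided.
* No polytope volume estimation or vertex enumeration: areas are measured
  in 2-D projections only, so "reachable fraction" statements are always
  relative to a chosen plane.
* The rejection oracle is exact but exponential in dimension; above chart
  dimension 4 the Hit-and-Run sampler is validated only indirectly (by
  audits and the low-dimensional equivalences).
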
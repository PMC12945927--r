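---
title: "Network control of brain states and the rich club: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network control of brain states and the rich club}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richclubnct)
```

## The question and the model

Structural connectomes contain a *rich club*: a set of high-degree regions
more densely interconnected among themselves than degree-preserving chance
allows. A long-standing hypothesis casts this club as the brain's control
core. `richclubnct` asks the quantitative version of that question with
linear network control theory: if the rich club is barred from injecting
control input — while remaining part of the dynamics, steerable by every
other region — how much harder does it become to maintain a brain state or
to steer the brain from one state to another? If the club were a driver of
control, barring it should hurt badly; if it is a passive backbone, barring
it should hurt *less* than barring an equally sized set of peripheral
regions.

### Dynamics and the stabilized system

Regional activity `x` evolves under the linear approximation
`dx/dt = S x + B u`, where `S` is a stabilized version of the weighted
adjacency matrix `A`:

    S = A / (1 + lambda_max(A)) - I

`lambda_max` is the largest eigenvalue of `A`, so every eigenvalue of `S`
lies in (-2, 0) and uncontrolled activity decays to the origin. This
normalization is one of several in use; it is exposed through
`stabilize()` so the matrix can be replaced wholesale if a different
convention is wanted. `B` is a selection matrix over the *control set*:
the regions allowed a private input channel `u`.

### Optimal control energy and stability

For a transition from state `x0` to state `xT` over horizon `T`,
`solve_optimal_control()` minimizes

    J = integral_0^T [ (xT - x)'(xT - x) + rho * u'u ] dt

with hard endpoint constraints `x(0) = x0`, `x(T) = xT`. Pontryagin's
conditions reduce this to a linear-affine two-point boundary-value problem
in state and costate, solved exactly with a single matrix exponential of
the Hamiltonian block matrix; the unknown initial costate comes from one
linear solve. Two numerical points matter:

* The horizon propagator is computed as the exact `n_steps`-th power of
  the per-step matrix exponential, so the endpoint solve and the sampled
  trajectory share one operator. With independent exponentials, their
  mutual inconsistency is amplified by the conditioning of the endpoint
  solve and can dominate the endpoint error.
* A reciprocal condition number below `1e-12` in the endpoint solve is
  reported as an uncontrollable or ill-conditioned control set rather than
  silently returning noise; the default endpoint tolerance is a relative
  `1e-4`. Both are configurable. Structurally symmetric ("twin") nodes
  outside the control set are a genuine way to hit this error on small
  random graphs.

Per-node energy is the trapezoid-rule integral of `u_i(t)^2` divided by
`n_steps`, and the reported energy is the mean over **all** N regions —
non-controllers contribute exactly zero but stay in the denominator. The
division by `n_steps` follows the convention of normalizing by the number
of timesteps spanned by the horizon; the pipeline scales `n_steps`
proportionally to `T` (a fixed step size), which is what makes energies
comparable across horizon settings. *Stability* of a state is the inverse
of the energy needed to maintain it (`x0 = xT`); the zero state is an
equilibrium and gets the sentinel `Inf`.

Restricting the control set can only raise the optimal cost (the
restricted problem's feasible controls are a subset), which yields two
exact monotonicity laws the tests assert at a `1e-9` absolute slack for
float noise: energy is non-increasing, stability non-decreasing, in the
control set.

### Rich-club detection

`weighted_rich_club_curve()` computes, per degree level k, the ratio of
the summed weight among nodes of degree > k to the sum of the equally many
strongest weights anywhere in the network — so the coefficient is 1 exactly
when the club's internal connections are the strongest available.
`normalized_rich_club()` divides by the mean curve of `n_nulls`
Maslov–Sneppen rewired graphs (weights travel with edges; degree sequence
and weight multiset are preserved exactly, asserted in tests) and assigns
each level a one-sided exceedance p-value with the plug-in formula
`#{null >= empirical} / n_nulls`; nulls whose level is undefined (no
surviving edges among the club) count as non-exceedances. The cutoff
`k_max_phi` maximizes the normalized coefficient within the significant
regime (per-level, uncorrected, no contiguity requirement — the strictest
reading we could defend; ties break toward smaller k). Membership is
degree **strictly greater than** the cutoff. When no level is significant,
the curve-based rule refuses and callers fall back to the top-k
definition, which breaks degree ties by strength and then node index so
membership is always deterministic.

The group-level club sizes itself by the mean individual membership
fraction — `round(f * N)`, half away from zero, reproducing the
22-of-219-regions arithmetic at f = 10.10% — and fills it with the nodes
most consistently assigned across subjects, frequency ties broken by mean
degree then node index.

### Spatial nulls and matched reference sets

`spin_rotations()` draws uniform random 3D rotations (QR of a Gaussian
matrix, determinant +1), applies each to left-hemisphere centroids and its
sagittal mirror conjugate to right-hemisphere centroids, and matches
rotated to original positions within each hemisphere by greedy
closest-pair assignment, which guarantees a hemisphere-preserving
bijection. This is a parcel-centroid adaptation of surface-rotation nulls:
centroids cannot represent parcel contiguity, a stated limitation rather
than a bug. Reference sets for the control comparison are the spun images
of the rich club (size-matched by construction); `profile_matched_set()`
and `sum_matched_set()` instead draw 500 random size-matched sets and keep
the one closest to the club's mean pairwise connectivity-profile
correlation or within-set connection sum, the two stricter null families.
The pool size of 500 is a desk-scale choice, configurable.

### Inference

The rich-club-excluded metric is compared per subject against the mean
over the reference-set-excluded runs. With a two-level within-subject
factor, the repeated-measures model with a between-subject covariate is
algebraically a covariate-adjusted paired comparison, and
`rm_anova_covariate()` implements exactly that: the per-subject difference
is regressed on the centered covariate and the condition F is the squared
intercept t on (1, n-2) degrees of freedom. The covariate is the *signed*
mean activation difference between the states (an absolute-value variant
is exposed). Calibration is part of the acceptance suite: type-I error
within [0.03, 0.07] at nominal 0.05 over 1000 null replicates, power
above 0.9 at a one-SD effect with 50 subjects. One-tailed paired t-tests
confirm directions post hoc; paired Cohen's d (`mean(d)/sd(d)`) is the
effect size, with a signed `Inf` sentinel for zero-variance differences.

Regional analyses rank regions by lesion impact — the energy increase, or
stability decrease, when that single region is removed from an otherwise
full control set — with rank 1 the most impactful region; average ranks at
ties are integerized by node index so every (task, measure) slice is a
permutation. Mean ranks are then compared across node sets, correlated
with regional maps (degree, participation coefficient, communicability),
and aggregated per network label, all against spin-permutation nulls.

## The synthetic cohort: what it emulates, what it does not

`cohort_config()` defaults define the study conditions: 10 subjects, 100
regions on a bi-hemispheric unit sphere (mirrored left/right, the symmetry
spin rotations preserve), distance-decayed connection probabilities with
FA-like weights in [0.1, 1], and a planted 10-region core that is fully
interconnected (`core_density = 1`) with weights boosted 1.5-fold (capped
at the weight ceiling). Subjects are jittered copies of one template: 20%
of edge weights resampled, 10% of pairs toggled, preserving symmetry, with
per-subject seeds `seed + 1000 * i`. Disconnected draws are regenerated
(bounded retries) rather than repaired, keeping the generative law clean.

Two design choices deserve their reasoning spelled out:

* **The passive core.** Brain-state pairs are built from the stabilized
  system's eigenmodes: state A mixes the slowest modes (slowest decay,
  hence cheapest to maintain), state B adds fast modes at weight
  `state_gap`, and both are scaled to equal norm, so A is the designed
  stable state — the solver itself verifies the asymmetry in >= 90% of
  draws. But the slowest mode of a core-heavy network is Perron-like and
  loads on the core; states built purely from it make the core an *active*
  carrier of state content, and barring it from control then hurts more
  than barring peripheral sets — the opposite of the empirical situation,
  where task contrasts concentrate outside the hub core. The
  `core_activation` parameter (default 0.2) attenuates both states on the
  planted core before normalization, making the core a passive backbone.
  This is the single most consequential generator parameter: at 1.0 the
  headline direction reverses.
* **No propensity heavy tail by default.** A multiplicative gamma
  propensity on connection probabilities (exposed as
  `degree_heterogeneity`) produces a heavy degree tail, but its hubs
  preferentially interconnect and form their own rich-club-like sets that
  compete with the planted core as ground truth; recovery experiments
  degrade badly. The default leaves the degree tail's right mass to the
  planted core itself.

The generator does **not** emulate tractography biases, empirical FA
distributions beyond their range, geometric surface meshes, task-semantic
state content, or subcortex. Passing tests therefore demonstrate that the
machinery is correct and that the paper's qualitative direction follows
from a planted passive core under linear dynamics — not that any specific
empirical effect size would be reproduced on real connectomes.

## Problem sizes and numerical defaults

The packaged analyses and tests run at desk scale, chosen to exercise
every code path with comfortable numerical margins: 50–100-region
networks, 100–200 rewired nulls per curve (the full-scale analysis uses
10,000), 10–50 spin permutations for network-level comparisons, 1000 for
regional tests (full scale 10,000), `n_steps` of 200–400 per unit horizon
in the pipeline and 1000 in the solver default. The solver's endpoint
accuracy is independently verified by forward Runge–Kutta integration of
the returned control; that oracle's own error is dominated by linear
interpolation of `u` between grid points and shrinks quadratically in the
grid, which sets the grid sizes used in the verification runs.

## Known limitations

* Parcel-centroid spin nulls preserve hemispheric assignment and rough
  geometry but not contiguity.
* The lesion scan solves 2(N+1) boundary-value problems per state pair;
  at hundreds of regions this is the dominant cost and parallelizes
  trivially across regions, which the package does not do.
* `individual_rich_club()` memberships can be small when the significant
  regime reaches into the top-degree tail (few nodes exceed the cutoff);
  the group definition absorbs this variance across subjects, but
  single-subject memberships should be interpreted with care.
* The repeated-measures layer covers exactly the two-condition design the
  study needs; it is not a general mixed-model interface.
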
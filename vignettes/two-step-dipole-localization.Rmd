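---
title: "Two-step single-dipole localization: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step single-dipole localization: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgidipole)
```

This vignette is the package's own account of the science it
implements: the forward and inverse models, the electrode-significance
machinery, every tunable that matters, and the design decisions that
were genuinely open.  Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The source model and its assumptions

During the first ~30 ms of an ectopic ventricular beat the activated
myocardial region is small, so its far-field is well approximated by a
single current dipole at a fixed position with time-varying moment.
The package therefore represents the cardiac source as one dipole
whose position is restricted to the vertices of an endo-epicardial
ventricular surface (the *candidate set*), and whose 3-vector moment
(mA·mm) is free at every sample.  This is deliberately not a
distributed-source (epicardial potential) model: the single-dipole
operator is a tall M×3 matrix with condition numbers close to 1, which
makes the least-squares inversion well posed without explicit
regularization — the opposite regime from classical ill-posed ECGI
formulations.

## Forward model: vertex-collocation BEM

The torso is a piecewise-homogeneous conductor bounded by closed,
outward-oriented triangulated surfaces; the exterior is insulating.
The surface-potential integral equation is discretized by vertex
collocation: potentials live at mesh vertices, and each triangle's
analytically computed solid angle is split equally among its three
vertices.  Two standard numerical devices are used:

* **Auto (diagonal) terms by the row-sum identity.**  The singular
  self-integral at each collocation vertex is never computed; it is
  fixed so that the angles a closed surface subtends at a point on
  itself total 2π.  Because a closed surface subtends exactly 4π or 0
  at interior/exterior points, the remaining row sums are exact up to
  round-off, which keeps the constant vector in the null space to
  machine precision.
* **Deflation.**  The insulated Neumann problem determines potentials
  only up to a constant.  A rank-one term `(1/N) 1 1ᵀ` on the
  outermost-surface block makes the system uniquely solvable; every
  solution is then re-referenced to zero mean over torso vertices.

The system is assembled and QR-factorized once per conductor and
reused for all candidate positions (the right-hand side of a dipole
source is purely geometric — the source-region conductivity cancels
between the integral equation's source term and the infinite-medium
potential).  Transfer columns are ordered X, Y, Z.

Accuracy is pinned to two independent oracles with closed-form
solutions: a central dipole in a homogeneous sphere
(φ = 3p·cosθ / 4πσR²) and an eccentric axial dipole at half radius,
whose surface potential is the Legendre series
φ(R,θ) = p/(4πσR²) · Σₙ (2n+1)(b/R)ⁿ⁻¹ Pₙ(cosθ).  The acceptance
suite computes the relative RMS error at icosphere refinements 2, 3
and 4 and asserts both that refinement 3 is below 5 % and that the
error decreases monotonically with refinement.

**Default conductivities** (all configurable): torso 0.2 S/m; lungs
0.25× torso; blood cavities 3× torso.  These ratios are the standard
piecewise-homogeneous cardiac model.  Setting an internal surface's
ratio to 1 must — and, by a tested invariant, does — reproduce the
homogeneous solution.

## The reference convention

Clinical BSPM systems record against a hardware common-mode electrode;
the forward model produces potentials up to an arbitrary constant per
sample.  Comparing the two requires a *unified* reference.  The
package adopts a zero-mean common reference everywhere: BEM outputs
are referenced over torso vertices, and at fitting time both the map
columns and the transfer-block rows are re-referenced to zero mean
**over the electrodes actually used**.  The last point was a genuinely
open choice for reduced-electrode fits (re-reference over the subset
vs. the full montage); the subset convention was chosen because it
keeps the map and the transfer rows in the same affine subspace, which
makes the RRE independent of the recording reference and makes a
restricted fit exactly equal an independent run on a
truncated-montage conductor (a tested invariant).

## Inverse solution and RRE

For a candidate block T and map Φ_B, moments are `pinv(T) %*% Φ_B`
with an SVD pseudoinverse (cutoff 1e-12·σ₁ — blocks are 3-column and
well conditioned, so the cutoff only guards degenerate phantoms, and
tripping it is recorded as a warning).  The relative residual error
RRE(t,j) = ‖Φ_B − Φ_C‖₂/‖Φ_B‖₂ per sample is scale-free and bounded
in [0,1] because Φ_C is an orthogonal projection of Φ_B.  The winner
is the global minimum over (t, j); ties break to the smallest sample
index, then the smallest position index — arbitrary, but deterministic
and platform-independent.  Moments are retained for all T samples at
the winning position, not only the winning sample, for diagnostics.

A zero-norm map column makes the RRE undefined; the fit refuses such
input naming the offending sample rather than silently returning 0/0.

## Electrode significance and the greedy order

Significance is a property of the *operator*, not of the recorded
signals: row subsets of the winning position's transfer matrix are
scored by criterion A (σ₁/σ₃, minimized), B (σ₁σ₂σ₃, maximized) or C
(σ₁+σ₂+σ₃, maximized).  The ranking has two stages:

1. **Exhaustive 4-subset initialization.**  All C(M,4) quadruples are
   enumerated (10,668,000 at M = 128).  This is feasible because each
   score needs only the 3×3 Gram matrix of the subset — a sum of four
   precomputed rank-one row products — with criterion B a determinant
   and A/C closed-form symmetric eigenvalues; the loop is compiled
   (Rcpp).  Equivalence of the Gram path with direct SVD to 1e-8
   relative accuracy is a tested invariant, not an assumption.
2. **Greedy augmentation.**  Each step adds the electrode that best
   improves the criterion; each candidate evaluation is a rank-one
   Gram update plus a 3×3 LAPACK eigendecomposition.  Local optimality
   of every step is verified against an SVD-only brute force in the
   tests; global optimality is explicitly *not* claimed.

Numerical policies: ties everywhere resolve to the lexicographically
smallest index set (exhaustive stage: first strict improvement in
enumeration order; greedy stage: smallest electrode index), so results
are bit-reproducible.  When σ₃ < 1e-12·σ₁, criterion A receives a +Inf
sentinel — the subset is maximally distorted, and the sentinel keeps
the ordering total without special-casing callers.  Because appending
a row can never decrease a singular value, B- and C-score sequences
must be non-decreasing along the greedy path; this is asserted on
every run as an internal-consistency check.

The occurrence analysis keeps the best `floor(fraction·C(M,4))`
quadruples (106,680 at M = 128, fraction 0.01) and counts electrode
membership; counts always sum to 4× the retained number.

## The two-step pipeline

Step one scans all electrodes; the greedy order is computed at the
*estimated* origin (the working assumption is that significance varies
slowly with source position, so the order at the estimate is close to
the order at the truth); step two re-scans the **full** candidate
surface using only the top-k electrodes.  Restricting the candidate
set to a neighborhood of the first solution was considered and
rejected: the second solution must be free to move far when the
reduced montage supports a different optimum, and the unrestricted
scan is what makes that observable.  Default reporting uses k = 32,
64 and M.

With very few electrodes the RRE surface over candidates flattens and
the minimum becomes meaningless.  Rather than suppressing small-k
results, each fit carries a flatness diagnostic — the ratio of the 5th
percentile to the median of per-candidate RRE; values near 1 mean "no
identifiable minimum, do not trust this k".

## The synthetic phantom

`phantom_spec()` defines the study conditions; its defaults are fixed
and are what the tests and acceptance script run under:

| parameter | default | rationale |
|---|---|---|
| torso semi-axes | 150 × 100 × 300 mm | adult torso scale, long axis z |
| heart surface | 35 × 35 × 40 mm at (0, 40, 30) | ventricle-sized, anterior-left, inside the chest band |
| torso / heart refinement | 3 / 2 (642 / 162 vertices) | BEM error well under 5 % (tested); 162 candidates keep the full-sweep inverse-crime test exhaustive yet fast |
| montage | 16 strips × 8 electrodes, z-fraction 0.25–0.75 | the 128-electrode strip-montage geometry of multi-lead BSPM systems |
| map | 30 samples at 1000 Hz | the averaged ectopic beat's first 30 ms |
| moment | fixed random unit direction, linear magnitude ramp, peak 10 mA·mm | minimal signal consistent with a fixed-position source of varying magnitude/orientation; the ramp mimics early-activation growth |
| SNR | 20 dB (global, on the vectorized clean map) | the averaged-beat noise level is not a published quantity; 20 dB is a realistic post-averaging figure and is deliberately a free knob |
| conductivities | 0.2 S/m; ratios 0.25 / 3 | standard piecewise-homogeneous model |

Two seeds are separated on purpose: `seed` drives only the noise draw,
`direction_seed` the moment direction, so replicates across noise
seeds share the identical clean map (a tested seeding contract).

**What the phantom does not emulate** — and hence what passing tests
do not show about clinical data: anatomical ventricular geometry and
CT segmentation error; electrode-position digitization error;
correlated (muscle/mains) noise rather than i.i.d. Gaussian;
beat-to-beat variability and imperfect beat averaging; and any
mismatch between the forward model used for simulation and inversion.
The default configuration is a deliberate *inverse crime* (same BEM
stack for both) so that the algorithmic chain can be verified exactly:
noise-free recovery must be perfect on every candidate vertex, which
the acceptance suite sweeps exhaustively.  An honest-model variant is
available by simulating on a refined mesh (`refine_heart`,
`refine_torso` are per-spec) or on the inhomogeneous conductor and
inverting with the homogeneous one; localization errors then become
nonzero and model-dependent, qualitatively mirroring
homogeneous-vs-inhomogeneous comparisons on clinical data.

## Problem sizes and determinism

The shipped tests run the full study conditions: M = 128 electrodes
(all 10.67M quadruples enumerated in compiled code), J = 162
candidates, 30-sample maps, 10 noisy replicates for the
reduced-electrode comparison, and sphere oracles up to 2562 vertices.
These sizes were chosen so the whole suite is exhaustive where
exactness is claimed (every candidate vertex, every greedy step)
rather than sampled.  All stochastic tests fix seeds; the pipeline
itself is deterministic for fixed inputs, which is itself a tested
invariant.

## Known limitations

* Single-dipole source only; no multi-dipole or distributed inverse,
  no activation-time imaging, no Tikhonov machinery (not needed in
  this well-conditioned regime).
* Isotropic, piecewise-homogeneous conductivities; no anisotropy.
* The exhaustive stage is O(M⁴): full enumeration at M = 128 is
  seconds, but cost grows steeply (M = 256 is ~17× more work);
  beyond that a subsampled initialization would be required.
* The greedy order is locally optimal by construction; no claim of
  global subset optimality is made or tested.
* Mesh I/O covers ASCII PLY, OFF and ASCII/binary STL; meshes must be
  closed, consistently orientable 2-manifolds — open scans must be
  repaired upstream.
* Indices are 1-based throughout the R API (file formats keep their
  native 0-based conventions on disk).
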
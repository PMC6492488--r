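---
title: "Comparing and clustering lattices with Selling scalars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and clustering lattices with Selling scalars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sellingr)
```

## The representation

A primitive unit cell (a, b, c, α, β, γ) determines the Bravais tetrahedron:
the three cell edge vectors **a**, **b**, **c** together with the body
diagonal **d** = −(**a** + **b** + **c**), which sum to zero. The six pairwise
dot products among these four vectors,

s = (**b**·**c**, **a**·**c**, **a**·**b**, **a**·**d**, **b**·**d**, **c**·**d**)  (Å²),

are the Selling scalars; `sellingr` treats them as a vector in a
six-dimensional Euclidean space, S6. Unlike cell parameters (a mix of lengths
and angles) or the metric-tensor space (squared lengths and inclined axes),
the six coordinates are of a single kind and the axes are orthogonal. The
same data can be folded into three complex numbers, C3, pairing each scalar
with its "opposite" (the scalar of the complementary vector pair):
c₁ = s₁ + i·s₄, c₂ = s₂ + i·s₅, c₃ = s₃ + i·s₆. Nothing is gained or lost in
the fold — round trips are bit-exact — but some operations are easier to
state on complex components.

A presentation is **Selling reduced** when all six scalars are ≤ 0 (all
inter-axial angles, including those to the body diagonal, are non-acute).
Every lattice has such a presentation, and for a generic reduced lattice
there are exactly 24 of them: the 4! permutations of the tetrahedron vectors
induce a 24-element group of component permutations of S6 (`s6_reflections()`).
In C3 these are the six permutations of (c₁, c₂, c₃) composed with the
exchange X(c) = i·conj(c) (swap real and imaginary part) applied to an even
number of components — 6 pure permutations and 18 with one X pair. The
package stores the matrices transcribed from the published table *and*
regenerates them from the vector permutations; the test suite asserts the two
sources coincide, which guards against transcription slips.

## Reduction and the edge transforms

If a scalar s_b is positive, one Delone step removes it: negate one vector of
the pair whose dot product is s_b, keep its partner, and add the negated
vector to the two remaining tetrahedron vectors. Each boundary has two such
steps (one per pair member), giving the 12 **edge transforms**; the two
variants of a boundary differ by one of the 24 reflections, and each
transform is its own inverse, so the same matrices "unreduce" a presentation
(`unreduce_random()`). Each step decreases −Σsᵢ = (|**a**|² + |**b**|² +
|**c**|² + |**d**|²)/2 by exactly the eliminated scalar, which bounds the
step count and guarantees termination; `selling_reduce()` eliminates the
largest positive scalar first (this maximizes the guaranteed decrease per
step; any order lands in the same 24-orbit, which the tests assert).

A point worth being precise about, because it shapes the API: the full 6×6
reduction matrices are involutions but **not orthogonal** — they carry an
additive column that implements the basis change. Restricted to their
boundary hyperplane s_b = 0 they act as permutations, and the combined
operator "transform the boundary projection, negate the axis component" is an
orthogonal signed permutation. Each `s6_edge_transform` object therefore
carries both forms: `matrix` (lattice-preserving, used by reduction) and
`vcp_matrix` (the isometric gluing map, used by the distance algorithms).
Claims that the boundary transforms preserve the metric refer to the second
form; the first preserves the *lattice* (the unit-cell volume, an invariant,
is checked in the tests to 1e−6 relative).

In C3 a reduction step has a three-part statement (`c3_reduce_step()`):
negate the offending part and subtract it from its partner part; add its
original value to both parts of the other two components; exchange one
scalar pair between those two components. The exchanged pair is determined by
the geometry — it consists of the two scalars coupling the *negated*
tetrahedron vector to the two non-pair vectors. For a real-part boundary this
is a cross (real↔imaginary) exchange; for an imaginary-part boundary it is a
same-part exchange. The suite verifies the complex-arithmetic route against
the matrix route for all 12 transforms on random inputs; this
cross-representation agreement is the package's central self-consistency
check.

### Canonical form

Within the reduced orthant, `canonical_presentation()` picks one
representative of the 24-orbit: components sorted by non-decreasing
magnitude (|c| is X-invariant, so sorting commutes with the exchange), then
real ≤ imaginary enforced on the first and second components by X pairs.
Exact ties are broken lexicographically on real then imaginary parts, making
the map deterministic; the part order of the third component is a consequence
of the group constraint, not a free choice. The canonical form collapses the
24-fold ambiguity only: a lattice sitting exactly on a sign boundary has
further reduced presentations (new bases generated by the boundary
transform) that are distinct 24-orbits. Deciding "same lattice" across that
degeneracy is the metric's job.

## Distances

The reduced orthant carries the Euclidean metric, but shortest paths between
lattices may leave it through a boundary, where the gluing is isometric yet
non-diagonal — the boundaries are not mirrors, so the naive Euclidean
distance between reduced representatives can overestimate. Two constructions
recover minimal one-boundary paths:

* **Virtual Cartesian points** (`dist_vcp1()`): the VCP of p for boundary b is
  the signed-permutation image `vcp_matrix %*% p` — the transform applied to
  p's boundary projection minus its axis component. The distance from q to
  that point equals the length of the optimal path from q to p's lattice
  crossing boundary b once (unfold the crossing: the operator is orthogonal).
  The candidate set is the 24 reflections of p and of its six VCPs — 168
  points; the implementation evaluates both argument orders and keeps the
  smaller, restoring symmetry. Only variant-1 VCPs are needed: a variant-2
  VCP is a reflection of the variant-1 VCP, and reflections are applied
  anyway (asserted in the tests).
* **Two-boundary solutions** (`dist_vcp2()`): the minimum over all pairs from
  the 168-point set of one input and the 7-point set (point + six VCPs) of
  the other. It never exceeds the one-boundary value.
* **Tunneled mirrored boundaries** (`dist_mirror()`): touch a boundary at the
  classical mirror point (heights divided proportionally along the projected
  chord), then continue at no cost from that point's transformed image,
  minimizing over the 24 reflections of the image and of the second point,
  against the direct reflection distance. Because the optimal crossing point
  divides the chord to the *transformed* projection rather than the raw one,
  the proportional construction is an upper bound: dist_vcp1 ≤ dist_mirror ≤
  the plain reflection minimum, with equality of all strategies on interior
  pairs. The tests verify `dist_vcp1` against an independent numerical
  geodesic search (direct minimization over boundary crossing points).

`cs6dist()` is the user entry point: it accepts cells or raw S6 vectors,
reduces internally, and dispatches (default `vcp1`). The value is symmetric,
non-negative, zero iff the inputs are one lattice, and invariant under
reflections of either input. It is a minimum over a restricted path family:
the triangle inequality is *not* guaranteed and is deliberately never
asserted. Distances are in Å²; `normalize = TRUE` divides by |p| + |q| for a
scale-free variant (plumbing for clustering, off by default).

### How often do two boundaries matter?

`mc_two_boundary_experiment()` samples pairs of random reduced vectors,
computing one- and two-boundary distances for each. The sampling
distribution matters a great deal here, and the experiment's definition is a
design decision of this package: components are drawn **uniformly in the
reduced (all-negative) orthant**, which spans near-boundary and interior
regimes (every such draw is also a realizable lattice). Under this protocol
roughly 1% of pairs are improved by the two-boundary construction, and the
median relative improvement among improved pairs is a few percent (run
`scripts/acceptance.R` to reproduce). The alternative of reducing random
*cells* was examined and rejected as the experiment's default: generic
reduced lattices hug the boundaries (median smallest |component|/norm ≈
0.02), which multiplies tiny improvements — ~7.6% of pairs improved with
median improvement ~0.1% — and no longer reflects a balanced sweep of the
cone. The cell-based sampler remains available via `sampler = "cells"`.

## The Follower

`follower_trace()` draws a straight segment from an unreduced point to its
reduced image, Selling-reduces each of `n_samples` evenly spaced samples
(default 200), and records the distance to the endpoint. Both ends are the
same lattice as the endpoint, so a correct metric yields zero there;
in between the trace should be continuous, with slope breaks only at
boundary crossings. `follower_qc()` checks endpoint-zeroness (tolerance
1e−8·|start|), continuity, and counts slope-sign breaks.

The continuity bound deserves a note. The distance is an exact 1-Lipschitz
function of the point it is evaluated at — every candidate map is an
isometry — but the *evaluated* point is the reduced sample, and the reduction
matrices have norm > 1, so the reduced representative can move up to a few
times faster than the raw segment (ratios up to ~3 are routine for starts
two or three unreduction steps out). Reducing samples first is nevertheless
the right choice: without it, endpoint zero cannot hold for multi-step
unreduced starts (`reduce_samples = FALSE` exposes the raw-segment scan).
The QC therefore compares each jump against the distance actually moved by
the evaluated points, floored at the segment step — a bound that is provable
for a correct metric and still catches injected faults — and reports the raw
jump/step ratio as a diagnostic.

## Synthetic cells and clustering

`generate_cells()` makes the package testable without any external data:

* `random` — basis vectors with independent uniform random directions
  (unit-sphere draws with |det| ≥ 0.2 to exclude near-degenerate bases) and
  edge lengths uniform in 10–100 Å, a range typical of small-molecule to
  protein cells. (Building an orthonormal frame via QR was considered and
  rejected: it fixes all angles at 90°.) Validity is guaranteed by
  construction rather than by rejection-sampling angles.
* `perturbed` — each basis vector of a parent cell displaced by an isotropic
  Gaussian of σ times its length: a single relative noise knob that moves
  lengths and angles together, emulating per-image cell scatter in serial
  crystallography. σ = 0 returns exact copies.
* `unreduced_presentations` — 1–k random inverse edge transforms plus a
  random reflection: alternative presentations of one lattice, useful for
  testing that any metric worth its name returns zero.

What the generator does *not* emulate: centered lattices (inputs are assumed
primitive), anisotropic or correlated measurement error, outlier cells from
mis-indexed images, and mixtures with unequal cluster sizes. Passing the
recovery tests therefore demonstrates metric and linkage correctness, not
robustness to every real-data pathology.

`distance_matrix()` reduces each cell once and fills a symmetric
`dist` object; `cluster_cells()` runs `stats::hclust` (average linkage by
default, the common choice in cell-based pre-clustering; single and complete
are available) with deterministic tie-breaking, cut by count or height.
The standard two-polymorph benchmark in the tests — 20 + 20 cells around
(10, 12, 20, 90, 90, 90) and (11, 13, 21, 90, 90, 95) at σ = 0.2% — is
recovered exactly (adjusted Rand index 1), identically for the one- and
two-boundary metrics.

## Numerical choices

* Angles are degrees at the I/O boundary, radians internally; right angles
  are kept exact via `cospi`/`sinpi`, so orthorhombic cells map to S6 vectors
  with exactly three zero components.
* Reduction tolerance: 1e−10·|v| (relative), iteration cap 1000; exceeding
  the cap is an error naming the last state, the signature of degenerate
  input.
* Cell validation: metric-tensor eigenvalues must exceed 1e−10 of the
  largest; reconstruction from scalars refuses non-realizable vectors
  (non-positive implied squared lengths, cosines outside (−1, 1)) with an
  explicit error rather than NaN.
* Squared distances are computed on explicit differences; the expanded
  ‖x‖² + ‖y‖² − 2x·y form was removed after it cost half the significant
  digits for near-coincident points.
* Problem sizes used by the test suite: 10,000 Monte-Carlo pairs, 10,000
  random reduction inputs, 100 Follower traces, 1000 round-trip cells —
  chosen to exercise the asymptotics while keeping a full run in a few
  minutes on one core.

## Known limitations

* The metric is a minimum over one- and two-boundary path families; paths
  through three or more boundaries are not searched (they matter for fewer
  than 1% of uniformly drawn pairs, by the experiment above).
* No triangle inequality is guaranteed, so tree methods that require a true
  metric space should be applied with that caveat.
* Centering is out of scope: inputs are taken as primitive cells.
* `canonical_presentation()` does not collapse the extra presentations of
  lattices lying exactly on a sign boundary (use the metric for identity
  tests).
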
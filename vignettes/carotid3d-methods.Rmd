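---
title: "Methods: slice-location registration, Bezier smoothing and contour lofting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice-location registration, Bezier smoothing and contour lofting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotid3d)
```

carotid3d reconstructs 3D carotid lumen and wall surfaces from marked
contours on multi-sequence black-blood MRI. This vignette documents the
models and procedures, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the
synthetic phantom does and does not demonstrate.

## The imaging setting

A carotid plaque protocol acquires five sequences of the same neck:
three spin-echo black-blood stacks (T1, post-contrast T1, T2) with a
thick inter-slice gap, and two 3D acquisitions (TOF angiography,
MP-RAGE) with a thin gap. The working threshold between the two regimes
is **1.8 mm** (`gap_threshold`, configurable): spin-echo stacks
typically sit above it, 3D stacks below. All spatial bookkeeping uses
the DICOM *Slice Location* tag (mm along the scan axis); sequence
identity comes from the *Series Description* tag through ordered
keyword rules (MP-RAGE before TOF before T2 before contrast-T1 before
T1), never from folder names, so renaming study sub-directories cannot
change the classification.

Slices are sorted ascending by Slice Location; a file lacking the tag
falls back to the z component of *Image Position (Patient)*, then
*Instance Number*, and a series mixing fallback keys is rejected rather
than silently mis-ordered. The per-series gap is estimated as the
**median** of consecutive location differences, which tolerates a
single irregular pair without shifting the estimate.

Display conversion maps rescaled stored values (slope/intercept
applied) linearly onto 0–255 with **round-half-up then clamp**. The
mapping is fixed so that any optimized implementation can be checked
bit-exactly against the definitional per-pixel loop; the test suite and
the acceptance script both perform that comparison on random 512×512
16-bit frames.

## Registration by slice-location arithmetic

Registration here is deliberately not image registration: no intensity
metric, no deformation, no in-plane alignment. The user (or the
pipeline, automatically) selects a *primary* sequence — the one marking
is performed on — and an initial slice in each secondary; the
*rationalization* step then forces the five series to identical slice
counts, identical gaps and aligned locations:

* A secondary whose gap is below `gap_threshold` while the primary's is
  at or above it is **decimated**: for each primary position the
  original slice nearest to (primary location + per-series offset) is
  kept, where the offset is the location difference of the two initial
  slices. Ties keep the lower index, and the search is constrained to
  increasing indices, so the retained correspondence is strictly
  monotone. On series of up to 12 slices this greedy nearest rule is
  tested for equality against exhaustive minimization of the summed
  location error over all monotone subsequences.
* A secondary already at or above the threshold is retained one-for-one
  from its initial slice.
* All series are then truncated to the shortest resulting length
  (`allow_truncation`, default on), so mismatched spatial coverage
  shrinks the common grid instead of failing.

Three design choices deserve explicit statement. First, a secondary
contributes a position only while the target location lies **inside its
coverage span**: nearest-slice matching is interpolation, never
extrapolation beyond the last acquired slice, which keeps the truncated
grid honest when one sequence covers a shorter neck segment. Second,
decimation is performed independently per thin-gap series rather than
by strictly alternating removals between the two 3D sets; independent
nearest-location decimation reaches the same postcondition
deterministically and does not depend on processing order. Third, the
rationalized result must actually satisfy the postconditions — equal
counts, per-series gap within 1e-6 mm of the primary's, per-position
location agreement within `location_tolerance` (default: half the
primary gap) — and an input geometry that cannot meet them raises an
error rather than returning a near-miss. In particular, gap pairs with
a non-integral ratio (a 1.8 mm primary against a 0.5 mm secondary)
admit no uniform common grid: decimation then produces irregular
retained spacing and the operation reports the incompatibility. A
thin-gap primary over thick-gap secondaries fails the same way, since a
thick stack cannot be densified to a thin grid.

## Marking model

Contours are closed polygons in pixel coordinates — x along columns, y
along rows, 0-based, y increasing downward; millimetres enter only at
`to_xyz()`, which scales by pixel spacing and appends the slice
location as z. Orientation is normalized at closing time to clockwise
as seen on screen, decided by the shoelace signed area; normalization
is a projection, so closing twice never changes point order again.
Consecutive duplicate points are dropped, edits (insert at the
brute-force nearest edge, move, delete) re-assert closure and
orientation, and a closed layer needs at least three points. Layers are
held in a stack ordered by slice location with explicit prev/next
links, validated after every mutation; the anatomical invariant that
the wall polygon encloses every lumen vertex on a shared slice is
enforced with a ray-casting point-in-polygon test.

Propagation to the secondary sequences copies point lists verbatim to
the corresponding slice (per the registration table) — no resampling —
and warns if pixel spacings differ. Marking may cover only part of the
stack; lofting requires at least two consecutive marked layers.

## Quadratic Bezier smoothing

Marked points are sparse; the smoother densifies each polygon edge with
a quadratic Bezier segment. The quadratic is preferred over the cubic
because it cannot overshoot: every curve point lies in the convex hull
of its three defining points, and the curve interpolates both marked
endpoints exactly (at `t = 0` and `t = 1` the other polynomial terms
vanish, so preservation is bit-exact, not approximate). The cubic
evaluator is retained for two purposes: as a comparison utility showing
the overshoot that wide control points produce, and as the oracle for
the affine-combination identity — the cubic equals
`(1−t)·B_quad(M₁,C₁,C₂) + t·B_quad(C₁,C₂,M₂)` — which the tests verify
to 1e-12 over a thousand random segments.

How the control point is derived from marked points is an open design
choice; carotid3d uses neighbor-tangent averaging: the tangent at a
vertex is the normalized central difference of its cyclic neighbors,
and the edge's control point is the mean of the two points reached by
following each end's tangent a fraction `tangent_scale` (default 1/3)
of the edge length. This is deterministic, parameter-light, and tight:
smoothing a regular 16-gon inscribed in a circle of radius 10 keeps all
128 densified points within 0.7 % of the radius, comfortably inside the
3 % band the acceptance checks require. Sampling is uniform in `t`
(`samples_per_segment` points per edge, default 8), not in arc length;
for the short, nearly-straight edges of a marked vessel contour the
difference is negligible and uniform-`t` keeps marked points exactly at
sample positions.

## Lofting and meshes

Stitching two stacked contours into triangles requires a vertex
correspondence the marking process does not provide (layers may have
different point counts). Each smoothed contour is therefore resampled
to `ring_samples` points (default 64) uniformly by cumulative arc
length, starting at a deterministic anchor — the vertex with the
largest x relative to the centroid, ties to the smallest y — so that
index i on one ring faces index i on the next and repeated runs are
byte-identical. Adjacent rings are stitched quad by quad, each quad
split along the same diagonal; texture coordinates are cylindrical
(u around the ring, v along the stack); vertex normals are
area-weighted averages of incident face normals oriented outward from
the ring centroid. End caps (triangle fans about the ring centroid) are
off by default, matching an open vessel segment; capped meshes are
closed 2-manifolds (Euler characteristic 2, every edge on exactly two
faces, consistent winding) and support signed volume by the
divergence-theorem tetrahedron sum — positive for outward winding,
negative if flipped, and refused on open tubes. Branching topology
(a carotid bifurcation putting two lumen rings on one slice) is out of
scope: one ring per layer per stack.

OBJ export writes `v`/`vt`/`vn`/`f` at full decimal precision and
round-trips losslessly; binary STL round-trips to float32. Volumes
computed from inscribed polygon rings slightly underestimate the
analytic value (a factor `cos²(π/N)` for a circle), which the volume
tests use as a lower bound.

## The phantom: what it emulates, what it does not

The phantom writes genuine DICOM files (explicit-VR little endian,
16-bit monochrome) for a tubular vessel: background 100, lumen disk
400, wall annulus 900 in stored units, plus Gaussian noise (sd 20,
clipped to 0–4095) from a per-slice seeded stream so output is
reproducible byte for byte. Its default protocol is the canonical
two-regime study — T1/T1CE/T2 at gap 2.0 mm × 20 slices, MPRAGE/TOF at
0.5 mm × 80 slices, 128×128 pixels at 0.5 mm spacing — and it emits
ground-truth lumen/wall contours (32-point regular polygons on the true
circles, on the thick grid) alongside the images. Intensities and noise
exist only to make slices visually plausible; the geometric pipeline
consumes the truth polygons, mirroring how a human marker, not a
segmentation algorithm, produces contours in the intended workflow.

What passing tests on the phantom shows: the registration arithmetic,
smoothing bounds, mesh topology and volume recovery (within 3 % of
π r² h over randomized radii) are correct on exactly-specified
geometry. What it does not show: robustness to real scanner data —
motion, bias fields, plaque component heterogeneity, non-circular and
bifurcating vessels, vendor-specific DICOM quirks beyond the tag set
exercised here.

## Problem sizes and determinism

Tests and the acceptance script run the default phantom study
(220 slices), 512×512 conversion frames, 1000-segment Bezier property
sweeps, rings of 8–128 samples, and 5 randomized radius draws for
volume recovery; these sizes were chosen to exercise every code path at
the study conditions above while keeping a full run in the order of a
minute. Every stochastic step draws from an explicit seed; the pipeline
itself contains no randomness, which is why repeated runs must be — and
are tested to be — byte-identical.
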
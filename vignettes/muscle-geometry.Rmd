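---
title: "Muscle geometry from polygonal meshes: centroids, lines of action, and mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle geometry from polygonal meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoline)
library(tibble)
```

## The model

`myoline` treats a muscle as a closed polygonal surface (`poly_mesh`): an
ordered vertex list plus faces of three or more vertex indices, wound
counter-clockwise seen from outside, with a length unit tag (mm, cm or m).
Three quantities are derived from it.

**Attachment centroids.** An attachment area is a subset of faces
(`face_selection`), selected by index file or OBJ group. Faces are
triangulated (quads split along the first diagonal, larger polygons fanned
from their first vertex); each triangle contributes its Heron-formula area
as weight and its vertex average as position, and the attachment centroid
is the area-weighted mean. This is an *extrinsic* mean: for strongly
curved patches (e.g. a hemispherical attachment) it lies off the surface,
which is the intended behaviour — it anchors a straight modelling axis,
not a point on the bone.

**Line of action.** Given origin and insertion centroids, `estimate_loa()`
slices the belly with `n_slices` planes perpendicular to the
origin–insertion axis, placed at interior parameters $t_i = i/(n+1)$ so
that no plane coincides with an attachment cap (inclusive placement is
available via `include_endpoints`). Each slice is the exact planar
cross-section of the mesh: triangle–plane intersection segments are
chained into closed loops, and the slice centroid is the area-weighted
centroid over all loops. The threaded path (origin centroid, slice
centroids, insertion centroid) is the LoA; `smooth_loa()` converts it to a
cubic spline curve and `arc_length()` measures MTU length.

**Mass.** `mesh_volume()` uses the signed origin-tetrahedron sum over the
triangulated surface, requiring a closed, manifold mesh (checked by
`validate_mesh()`); inward winding is detected by the negative signed sum,
corrected by absolute value, and flagged. `mass_from_volume()` converts to
m³ and multiplies by a homogeneous muscle density, 1060 kg/m³ by default;
`composite_mass()` adds a tendon compartment at 1120 kg/m³ (about 5%
denser). Whether and how a muscle is partitioned into muscle and tendon is
always an input — the package never infers it, and the default is
all-muscle.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `n_slices` | user-set | – | more slices resolve curvature but push the end planes closer to the attachments (see limitations) |
| `muscle_density` | 1060 | kg/m³ | standard literature value for fresh muscle |
| `tendon_density` | 1120 | kg/m³ | used only by `composite_mass()` |
| `smoothing` | 0 | – | 0 interpolates the path; larger values fit a least-squares cubic B-spline with roughly `n/(1 + smoothing)` degrees of freedom |
| `weld_tol` | 1e-9 | model units | STL vertex welding grid |
| `unit` | mm | – | carried on every mesh; conversions happen only at the mass and OpenSim-export boundaries (metres) |

## Numerical choices

- **Triangulation tie-break.** For non-planar quads the two diagonal
  splits differ; the (v1, v3) diagonal is always used, so results are
  deterministic. For planar faces area, volume, and centroids are
  independent of the split (tested).
- **Degenerate faces.** Triangles whose squared area is below
  $10^{-12}\times$ the squared bounding-box diagonal are excluded with a
  warning and zero weight, so near-collinear slivers cannot poison the
  Heron radicand (which is clamped at zero).
- **Planes through vertices.** The slice-plane offset is perturbed along
  its normal by $10^{-9}\times$ the bounding-box diagonal (doubling until
  clear), deterministically — no randomness is involved anywhere in the
  geometry.
- **Loop centroids.** Slice-loop centroids use the signed shoelace
  (fan-triangulation) formula in plane coordinates. For any simple planar
  polygon this equals the area-weighted centroid of an ear-clipping
  triangulation, so non-convex loops need no explicit ear clipping.
- **Multiple loops in one slice.** Disjoint loops are combined by area
  weighting by default, deliberately reproducing the centroid-drag
  behaviour near wide oblique attachments; `nearest_loop = TRUE` keeps
  only the loop nearest the origin–insertion chord instead.
- **Empty slices.** Planes that miss the belly are skipped with a warning;
  if more than half are empty the axis is judged to miss the muscle and an
  error is raised.
- **Smoothing splines.** Curve conversion uses a least-squares cubic
  B-spline parameterised by cumulative chord length;
  the fitted curve is linearly corrected so the endpoints (the attachment
  centroids) are preserved exactly at any smoothing level. Paths with
  fewer than four points fall back to linear interpolation.
- **Statistics conventions.** The Mann–Whitney W follows the first-sample
  rank-sum convention ($0 \le W \le n_x n_y$, midranks for ties), exact by
  full enumeration when both samples have at most 8 tie-free values, else
  a normal approximation with tie and continuity corrections. In
  Bland–Altman reports, "bias ± h" denotes the half-width of the
  t-based confidence interval of the bias; the limits of agreement
  (bias ± 1.96 SD) are reported separately. Within-range summaries centre
  the SD intervals on the reference mean, and "range ± 20%" means
  $[0.8\,\min,\ 1.2\,\max]$; both choices are the plain readings and are
  kept fixed rather than configurable guesswork. All tests are two-sided.

## The synthetic generator

`make_tube()` sweeps a circle along a parametric centerline using
parallel-transport frames (rotation-minimising, no twist), producing a
quad-strip tube with triangle-fan caps perpendicular to the end tangents,
and refuses radii that exceed the local curvature bound (self-intersecting
tubes). Its ground truth carries the centerline, cap centroids with their
face selections, and an analytic volume — $\pi r^2 h$ for straight
constant-radius cylinders, otherwise a $10^4$-interval composite-Simpson
integral of $\pi r(t)^2\,|c'(t)|\,dt$. `make_primitive()` supplies exact
cubes, icospheres and frusta; `make_oblique_muscle()` builds a rectangular
prism whose origin cap is tilted about the width axis, the geometry that
produces the LoA kink artifact, together with an exact closed-form slab
centroid oracle (`oblique_slice_centroid()`).

These fixtures emulate fusiform and curved bellies and angled attachments
with exactly known geometry. They do **not** emulate real anatomy:
no pennation, no multiple heads, no branching tendons, no scan noise,
no retopology artifacts. Passing tests therefore demonstrate that the
geometric operators are correct on clean closed meshes — not that a
particular anatomical reconstruction is accurate, which remains limited by
the quality of the input models.

## Problem sizes

The shipped tests and the acceptance script run the fixtures at moderate
resolutions chosen as realistic for sculpted muscle models: tubes of
48–96 rings × 48–64 sides, icospheres at subdivision 3–4, slice counts of
5–40, and statistical fixtures of 3–20 muscles. All of these complete in a
few minutes on a single core; resolutions are set in one place per fixture
and scale up without code changes.

## Known limitations

- **Near-attachment slice drag (the "kink").** Slices are placed along
  the straight origin–insertion axis. Where an attachment area is wide and
  angled to that axis, the end planes cut obliquely through the attachment
  region, and area-weighted slice centroids are dragged toward the side
  the cap leans. The oblique-prism fixture reproduces this exactly
  (matching its slab oracle to machine precision, with deviation growing
  monotonically in cap angle), and the same mechanism appears on the
  quarter-circle tube, whose caps stand at 45° to the chord: its worst
  near-cap slice deviation is about 2% of the tube radius at 20 slices and
  grows sharply when more slices push the end planes into the cap region.
  This is intrinsic to the slicing definition, not a numerical artifact;
  downstream musculoskeletal software can correct the path locally, or
  `nearest_loop`/fewer slices can be used near such attachments.
- **Extrinsic centroids** can lie off-surface for curved attachment
  patches (by design; documented above).
- **Straight-axis slicing** assumes the belly is star-shaped enough around
  the chord that perpendicular planes produce sensible sections; strongly
  C-shaped muscles violate this and should be handled with via-points
  downstream — wrapping surfaces and multi-path discretisation are out of
  scope.
- **Mass accuracy** is bounded by the homogeneous-density assumption;
  the tendon compartment helps only if tendon volume is supplied
  separately.

## A complete run

```{r example, eval = FALSE}
belly <- make_tube(function(t) c(12 * t, 2 * sin(pi * t)^2, 0),
  radius = 1, n_rings = 48, n_sides = 48, unit = "cm"
)
origin <- attachment_centroid(belly$truth$cap_selections$origin)
insertion <- attachment_centroid(belly$truth$cap_selections$insertion)
loa <- smooth_loa(
  estimate_loa(belly$mesh, origin, insertion, n_slices = 15),
  n_samples = 100, smoothing = 0
)
arc_length(loa, use_smoothed = TRUE)
export_loa(loa, "belly_path.xml", format = "osim_pathpoints")
mass_from_volume(as.numeric(mesh_volume(belly$mesh)), unit = "cm")
```
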
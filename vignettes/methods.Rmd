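---
title: "How swellkit measures facial swelling: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How swellkit measures facial swelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

swellkit turns three facial surface scans — pre-operative (T0), three days
(T1) and one week (T2) after surgery — into two quantitative swelling
outcomes per scan pair: a mean signed linear difference in millimetres and
an enclosed-volume difference in cubic millimetres, both restricted to the
operated hemiface. This vignette is the package's own account of the
geometry and statistics involved, of the parameters a user can reasonably
want to touch, and of what the validation suite does and does not
demonstrate.

## The measurement model

### Canonical frame

All quantities are defined in a canonical anatomical frame: millimetres,
right-handed, x from the subject's left to right, y posterior to anterior,
z inferior to superior. A scan enters this frame through named landmarks:
the Frankfurt plane (both porions plus the left orbitale) is made
horizontal, the midsagittal plane (through the nasion, orthogonal to
Frankfurt, containing the porion-midpoint-to-nasion direction) becomes
x = 0, and the origin lands on the porion midpoint. `orient_by_landmarks()`
computes this as a closed-form orthonormal frame construction; degenerate
landmark triplets (Frankfurt triangle area below 1 mm²) are rejected rather
than silently producing an ill-conditioned frame. Only T0 is oriented this
way; T1 and T2 reach the frame by surface registration onto oriented T0,
which mirrors how a clinician would process a scan series and keeps the
landmark burden to a single scan. When a pre-oriented reference surface is
available (for instance soft tissue segmented from an oriented CBCT), T0
can additionally be refined onto it with the same registration machinery.

### Registration

`icp_register()` is a trimmed point-to-surface iterative closest point.
Each iteration takes a seeded uniform subsample of source vertices (drawn
once, so the objective is fixed across iterations and runs are
reproducible), finds for each its nearest point on the target *surface* —
nearest point on triangles through a uniform-grid spatial index, not
nearest vertex, so registration accuracy is not bounded by mesh resolution
— discards the worst `trim_fraction` of correspondences by distance, and
updates the pose.

The pose update is staged. While the alignment is coarse, the update is the
closed-form SVD (Kabsch) fit to the foot points, which is robust to large
displacements. Once the per-iteration improvement falls below 5 % of the
current RMS, the update switches to Gauss–Newton steps on the
point-to-plane objective — squared distances to the target's tangent planes
at the foot points. The reason is empirical and reproducible with this
package's own fixtures: on a smooth head surface the point-to-point update
has a slow tangential-sliding mode and stalls at a few tenths of a
millimetre after a hundred iterations, while the tangent-plane objective
removes that mode and converges to numerical precision in a handful of
steps. The reported RMS is always the trimmed point-to-surface RMS, and the
returned transform is the best pose seen.

Trimming is what makes the procedure valid for this application at all: the
swollen cheek is a genuine anatomical change, and an untrimmed fit would
split the difference between the swollen and unswollen tissue, biasing both
the linear and the volumetric outcome. With the default
`trim_fraction = 0.10` the bump (a few percent of the face's surface) falls
entirely inside the discarded tail once alignment is close. Defaults:
`max_iterations = 100`, `rms_change_tolerance = 1e-4` mm,
`subsample_size = 5000`, `seed = 0`. Initialization is the identity, which
is adequate because scans are acquired in natural head position; the bound
assumed by the validation suite is 10° and 10 mm of misalignment.

### Region of interest

The operated-hemiface region is the intersection of four half-spaces, each
an axis-aligned plane in the canonical frame through one ROI landmark:
below the zygomatic arch, above the submandibular fossa, anterior to the
preauricular point, and on the operated side of the facial midline
(`side = "right"` keeps x at or below the midline plane under the axis
convention above). Anatomical boundaries are not planes, but planes through
the named landmarks are the simplest construction that two observers will
reproduce identically; that reproducibility is worth more here than
anatomical fidelity, since every comparison uses the *same* ROI. The ROI is
defined once on oriented T0 and applied to all registered scans — per-scan
ROIs would break the additivity of volume differences across pairs.

`clip_to_roi()` splits triangles exactly at each plane, interpolating
vertex attributes linearly, rather than keeping or dropping whole
triangles: the clipped patch's area and volume must not depend on how the
mesh happens to be tessellated at the boundary.

### Linear differences

For every vertex *p* of the later scan, the displacement is `p − q` with
*q* the nearest point on the earlier surface, and the signed distance is
`±‖p − q‖`, the sign taken from the earlier surface's outward angle-weighted
pseudonormal at *q* (face, edge and vertex feet get the face normal, the
edge-adjacent average, and the angle-weighted vertex normal respectively —
the standard construction that makes inside/outside classification exact
for watertight surfaces). Positive means the later surface lies outside the
earlier one: swelling. The earlier mesh's global orientation is normalized
from its signed volume first, so meshes with reversed winding cannot
silently flip every sign.

The summary is the plain arithmetic mean of signed distances over ROI
vertices. Signed, not absolute: tissue deficit must be allowed to cancel
excess, otherwise resolution between T1 and T2 could not come out negative.
Vertex-uniform, not area-weighted: the statistic then matches what
per-vertex mesh-statistics tools report, and scanner meshes are close to
uniform; an area-weighted variant (each vertex weighted by a third of its
incident triangle area) is available as an option. The colormap export
writes the field as a symmetric blue–white–red diverging map; the default
span is the 95th percentile of |signed distance|, so a handful of outlier
vertices cannot wash out the display.

### Volume differences

`mesh_volume()` implements the divergence theorem: the enclosed volume of a
closed oriented triangle mesh is `|Σ det(v₀,v₁,v₂)|/6` over faces. A
negative signed sum is reported as `orientation_flipped` rather than an
error. ROI-clipped patches are open along the cut; `close_mesh()` fills
each boundary loop with a triangle fan from the loop's centroid before
measuring, with winding chosen consistent with the adjacent faces.

Two numerical choices in the closing deserve record. First, the fan apex is
the *edge-length-weighted* centroid of the loop, not the plain vertex
average. The clip boundary can acquire many micro-segments where the cut
runs close to existing vertices; a vertex-averaged apex moves with vertex
density, and because the loop is non-planar, millimetre-scale apex motion
changes the enclosed volume by thousands of mm³. The length-weighted
centroid is a property of the boundary *curve*, not of its tessellation,
and makes patch volumes stable to sub-micrometre perturbations of the
input. Second, boundary loops are traversed sector-by-sector around each
vertex (rotating through the face fan), and any cycle that still revisits a
vertex — a pinched hole — is split into simple cycles, each with its own
apex; otherwise apex edges at the pinch would be shared by four triangles
and the result would not be watertight. Relatedly, `clip_by_plane()` snaps
an edge–plane intersection onto an endpoint when the interpolation
parameter is within 1e-9 of 0 or 1 and drops the resulting degenerate
slivers, so cuts through existing vertices cannot create coincident
duplicate vertices.

The pair outcome is the difference of the two independently closed patch
volumes, later minus earlier — not a boolean/CSG volume enclosed *between*
the surfaces. Difference-of-volumes is well defined for any pair of
non-crossing patches sharing the same clip planes, makes
`ΔV(T0–T2) = ΔV(T0–T1) + ΔV(T1–T2)` an exact identity (each scan's volume
is computed once and reused), and coincides with the between-surfaces
volume when the surfaces cross only inside the swelling region. Open scans
given directly to `mesh_volume()` require `auto_close = TRUE` explicitly;
an unexpected hole is more often a data defect than an intention.

## The synthetic study conditions

No clinical scans ship with the package, so every claim is validated on
synthetic triplets whose ground truth is known by construction.
`generate_head()` builds a watertight ellipsoid (semi-axes 70 × 90 × 100 mm,
a subdivided icosahedron, 2562 vertices at the default subdivision 4 —
edge length ≈ 6 mm, comparable to a consumer face scan after decimation)
with a deterministic landmark set laid out in the canonical frame.
`add_swelling_bump()` displaces vertices along the undeformed surface's
outward normals by a Gaussian `A·exp(−d²/2σ²)` of the *Euclidean* distance
to the bump centre — Euclidean rather than geodesic so the added volume has
an analytic handle (on a flat patch it is exactly 2πAσ²) computable
independently of the code under test. Scenario defaults emulate the
clinical course: A(T1) = 3 mm on the mid-cheek, resolving to A(T2) = 1 mm,
σ = 15 mm, each scan independently misaligned by up to 5° and 5 mm; the
ICP validation extends the misalignment bound to 10°/10 mm, and the
end-to-end validation sweeps A ∈ [1, 4] mm and σ ∈ [10, 25] mm.

The generator's ground-truth record reports the added volume two ways: the
whole-head value, and the value restricted to the scenario's ROI (clip the
undeformed and deformed canonical meshes, close, subtract). The
ROI-restricted number (`analytic_added_volume_*`) is the recovery target
for the pipeline, whose estimate is ROI-restricted by construction; with
σ = 25 mm a non-negligible Gaussian tail crosses the ROI planes, and
comparing an ROI-restricted estimate against a whole-head truth would
conflate that geometric truncation with pipeline error. The ground truth is
computed on the canonical, unperturbed meshes and therefore stays
independent of the registration being validated.

What the generator does *not* emulate: scanner noise textures (per-vertex
jitter exists as an opt-in flag, default off), missing data and occlusion
holes, expression changes, non-rigid drift between sessions, and real
facial topography (a nose is not a landmark here; the surface is smooth).
Passing the validation suite therefore demonstrates the geometry engine
and the pipeline logic, not robustness to every artifact of real
acquisitions — on clinical data the registration and the distance field
inherit the scanner's own accuracy floor.

## Independent oracles and what the suite checks

Each quantitative stage is checked against a computation that shares no
code path with it: volumes against the analytic sphere/ellipsoid formulas,
against a tetrahedron-decomposition oracle (signed tetrahedra to an
interior point, tolerance 1e-9 relative, 50 random smooth star-shaped
meshes), and — after hole-closing — against a compiled rasterisation
oracle that integrates surface crossings by parity over a 0.2 mm column
grid (tolerance 1 %, 50 seeded hole patterns). Registration is checked by
recovering seeded rigid motions (mean vertex error below 0.1 mm over 100
draws; below 0.5 mm on the unswollen hemiface when a 3 mm cheek bump is
present). The distance field is calibrated on concentric spheres (r = 50
vs 51 mm: +1.0 mm within 1 %, sign flipping on role swap). The end-to-end
check regresses estimated against analytic added volume over 20 seeded
scenarios and requires slope within [0.95, 1.05], exact volume additivity,
and the clinical sign pattern (onset positive, resolution negative) in
every scenario; a byte-identity check on the emitted report pins down
end-to-end determinism. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-chosen seed. Problem sizes
(subdivision 3–4 meshes, 20 scenarios, 50-mesh oracle sweeps) were chosen
so the entire suite exercises every stage at the study's mesh resolution
in about a minute of CPU.

## Known limitations

* Rigid registration only; genuine postural or expression changes between
  scans leak into the swelling estimate.
* Plane-bounded ROIs; a geodesically bounded region would follow anatomy
  more closely but is not reproducible from four landmarks alone.
* Fan closing assumes star-shaped boundary loops with respect to their
  length-weighted centroid; wildly folded clip boundaries could
  self-intersect the fill (not detected), though the plane-clipped patches
  this pipeline produces are far from that regime.
* The signed mean treats every ROI vertex equally; strongly non-uniform
  scanner tessellations would argue for the area-weighted option.
* Landmark placement error propagates into the frame and the ROI planes;
  the pipeline quantifies geometry given landmarks, it does not find them.
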
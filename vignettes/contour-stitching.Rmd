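---
title: "Stitching contour stacks into watertight surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching contour stacks into watertight surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourstitch)
```

## The problem

Automatic cortical reconstruction tools are calibrated on atlases of
well-studied species. For rare or unusually gyrified brains — cetaceans
are the extreme case — the only reliable segmentation is an anatomist
tracing closed contours around gray matter, white matter and the exposed
envelope on evenly spaced image slices. This package reconstructs closed
triangle meshes from such contour stacks and measures them; everything
here describes how, which knobs matter, and what the validation phantoms
do and do not demonstrate.

## Data model and conventions

A `contour` is a closed ring of 2D vertices (mm) at a fixed slice height;
a `contour_stack` is an ordered list of slice planes with a constant gap
`h` (mm). Coordinates are right-handed with slices stacked along +z, and
"clockwise" means negative shoelace area viewed from +z; all contours are
normalised to simple, clockwise rings on the way in (consecutive
duplicates within 1e-6 mm merged, self-crossings repaired). These
conventions are arbitrary but must be fixed somewhere: every orientation
decision downstream (band winding, cap winding, outward normals) reduces
to them.

Crossing repair resolves each crossing at its intersection point and
keeps the simple loop of largest absolute area. The alternatives —
rejecting the contour, or keeping all loops — are worse for traced data,
where a bow-tie is almost always a stylus slip enclosing a sliver;
discarding everything but the dominant loop is deterministic and
preserves the intended region. Slivers below about 1e-4 of the total area
are exactly the scale of such slips.

## The band search

Two contours on adjacent slices are joined by a ladder triangulation:
each triangle consumes exactly one contour edge, so a band has
`N_a + N_b` triangles and every contour edge appears in exactly one band
triangle (this *perfect cover* is what makes the assembled surface
watertight). With the anchor vertex pair fixed, the minimum-total-span-
length band is found by dynamic programming over the unrolled
`(N_a+1) x (N_b+1)` grid. The cost of a move is the length of the span it
creates; an area cost is provided as an alternative (`cost = "area"`),
and the cost interface is the natural extension point.

Minimum-cost ties are real (think of a square prism: either diagonal of a
wall quad gives the same length). They are broken deterministically:
advance the contour with more unconsumed vertices, then contour `a`. Any
fixed rule would do; determinism is the property that matters, because
byte-identical reruns are part of the package's contract.

### Self-avoidance

The unconstrained minimum can pierce previously built geometry when
sulci are deep and slices dissimilar. The search therefore runs
iteratively: build the DP-optimal band, scan its triangles in path order
against all accepted geometry (and the earlier part of the band itself),
mark the first offending move with infinite cost — a *retraction* — and
re-run. After `10 (N_a + N_b)` retractions (configurable) the anchor is
abandoned and the search restarts from the next pair in the
closest-to-furthest anchor list; the user can also pin the anchor. The
original formulation retracts moves inside a single incremental search;
re-running the DP with a growing set of banned moves explores the same
space (minimum cost subject to the accumulated bans) while keeping every
intermediate band optimal, and it degenerates to the plain DP on convex
inputs, where no retraction can ever trigger. If every anchor fails, the
unconstrained band is returned flagged — a visible quality signal, never
a silent one.

Intersection tests are exact triangle-triangle tests with a 1e-9 mm
tolerance; face pairs sharing a vertex are excluded, since adjacent
triangles always touch along shared edges and vertices, and the
zero-width bridge walls of merged contours touch by construction.

### Branching and nesting

Adjacent slices are first grouped by projected overlap (*shadow
casting*): two contours relate when their z-projections overlap with
positive area. The predicate is exact for simple polygons — any proper
edge crossing, a vertex strictly inside the other polygon (this catches
boundaries that cross exactly at shared vertices, which sampled
fold patterns produce routinely), or an interior point inside the other.
A bounding-box prefilter keeps it cheap. Positive-area overlap rather
than bounding-box overlap matters: adjacent gyri have interleaved boxes
but disjoint interiors, and merging them would weld folds together.

Within a group, a side holding several contours is merged into one
polygon by zero-width bridges at the closest admissible vertex pairs
(closest first, greedily for three or more), skipping bridges that would
cross a boundary. Bridge vertices are duplicated in the ring but mapped
to the same mesh vertex, so the two slit walls share their edge and the
saddle stays watertight. Nested contours in a group are matched by
containment-depth parity — outer walls (even depth) stitch to outer
walls, inner (odd) to inner — which is what anatomy wants for annular
gray matter: pial-to-pial, ventricular-to-ventricular. First- and
last-slice contours, and contours with no partner across a slice pair,
are capped by ear clipping; holes of nested regions are cut into the cap
with reversed bridges. Ear clipping treats zero-area ears as non-ears
rather than dropping the vertex: a cap must use every boundary vertex,
or its rim would not match the band edges and the mesh would leak.

After assembly the mesh is reoriented coherently (breadth-first flip
propagation over manifold edges) and each connected component flipped,
if needed, to non-negative signed volume, i.e. outward normals.

## Post-processing

The raw stitched surface is jagged in the ladder-like way voxelized
tracing produces, which inflates area (volume much less). The fixed
pipeline `smooth_pipeline()` is: reorient → close holes → simplified
isotropic remeshing → HC-Laplacian smoothing → Taubin smoothing.

* The remesher does the standard four sweeps (split edges above 4/3 of
  the target length, collapse below 4/5 where the link condition holds,
  flip toward valence 6, relax tangentially). It is deliberately
  *simplified*: there is no projection back onto the input surface, so it
  is flagged `remeshed = "simplified"`. Vertices whose incident face
  normals spread more than 40° (creases, cap rims) are kept in place by
  the collapse and relaxation passes — without this, rim rounding alone
  costs about 1% volume on a cylinder; with it, drift stays well under
  0.5%.
* HC-Laplacian smoothing (`alpha = 0`, `beta = 0.5`) and Taubin
  smoothing (`lambda = 0.5`, `mu = -0.53`, 10 iterations) use the
  standard literature constants; the upstream processing they emulate
  names the filters but not the parameters, so smoothed results are
  comparable in character, not bit-reproducible. Both preserve
  connectivity exactly, so V, E, F and the Euler characteristic are
  invariant — smoothing can never change topology.

## Analytical approximation

The slice-based rules are implemented verbatim: the per-gap slant-area
rule for lateral area, the conical-frustum rule for volume (exact for
linear-radius stacks, which the frustum phantom checks at 1e-9), and the
nesting-parity aggregation of areas and perimeters. Slices with no
contours inside a structure's range enter as `S = 0, P = 0` endpoints,
the AA analogue of capping. The lateral-area rule is applied as printed
even across branch events where `S_{n+1} < S_n`; its accuracy there is
inherited from the approximation itself, not from this implementation.
Derived metrics: `T = (V_t - V_wm)/A_t`, `GI = A_t/A_e` (reported at two
decimals, matching the precision of published summary tables), and
`gap_min ~ T` — a sulcus spans two cortical walls (`2T`) and
Nyquist-sampling that spatial frequency needs a slice gap of at most
`T`.

## Phantoms: what they emulate, and what they do not

All validation runs on deterministic phantoms with polygon-corrected
closed-form references (e.g. the inscribed N-gon area
`N r^2 sin(2*pi/N)/2`, not `pi r^2`), so tolerance budgets measure
stitching error, not discretisation error. The suite uses cylinders and
frusta (convex baselines; the metric-convergence check runs the 64-point,
20-slice cylinder and a x2 refinement, a size chosen to keep the full
suite under a minute per criterion), a sphere (curved caps), a torus with
its axis parallel to the slices (two contours mid-stack, one near the
poles — the branching case), a nested annulus (parity aggregation and
wall-matched stitching; its shell thickness `(R^2-r^2)/2R` is the AA
oracle), a gyrified tube `r(theta, z) = r0 + a sin(k theta) sin(q z)`
(deep folds for the self-avoidance audit and the resolution experiment:
with fold half-period 1.9 mm and 1 mm slices, keeping every other slice
undersamples the folds and total area drops strictly), a terraced
cylinder (vertices snapped to a voxel grid with the radius jumping half a
step between alternate slices — the ladder-like raw artifact), and a
two-slice knot case whose deep sulcus starts on opposing sides
(inconsistent tracing). Optional vertex jitter is seeded and restores the
caller's RNG state.

What phantoms do not show: real tracing error is correlated along a
contour, not i.i.d. jitter; real branch events are asymmetric; real
sulci are not sinusoids. Passing the suite demonstrates the geometry and
topology machinery, not segmentation quality — consistent with tracing
remaining the accuracy bottleneck in practice.

## Numerical choices

Planar predicates use orientation tests with a scale-aware epsilon
(1e-9 relative); the point-in-polygon test is even-odd ray casting, with
representative interior points taken from ear centroids rather than
centroids (centroids of concave or annular regions can fall outside, or
inside a nested contour — containment therefore also cross-checks the
reverse inclusion and breaks mutual containment by area). JSON stacks
are written at 17 significant digits so write/read cycles are bit-exact.
Degenerate inputs fail loudly: contours under 3 distinct points,
zero-area rings, partially overlapping same-slice contours, non-uniform
gaps, and non-watertight meshes passed to the volume integral all raise
errors rather than warnings.

## Known limitations

The self-avoidance search is complete only over ladder triangulations
with the tried anchors; a contour pair can in principle defeat it, which
is why flagged outputs exist (exit code 3 in the CLI). The remesher's
lack of surface re-projection trades a little fidelity for robustness.
The shadow-overlap graph uses connected components, so a chain of small
overlaps merges everything it touches. And the analytical approximation
assumes adjacent slices are similar; it degrades exactly where
reconstruction does — gaps wider than the structures being traced.
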
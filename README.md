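# contourstitch

Surface reconstruction and morphometry from stacks of manually traced
contours.

When a brain (or any other structure) cannot be segmented automatically —
no atlas, no training data, one rare specimen — an anatomist traces closed
contours around the regions of interest on evenly spaced image slices.
`contourstitch` turns such a contour stack into a watertight triangle mesh
and measures it: surface areas, enclosed volumes, cortical thickness and
gyrification index. It is aimed at comparative neuroanatomy workflows
(highly gyrified, non-model species where tracing is the only option), but
works for any stack of closed planar contours.

## Method

Each pair of adjacent slices is connected by a *band*: a ladder
triangulation in which every triangle uses exactly one contour edge and
two *spans* (edges connecting the slices). Among all
`C(N_a + N_b, N_a)` ladder triangulations anchored at a starting vertex
pair, the band minimising the **total created edge length** is found by
dynamic programming on the unrolled `(N_a+1) x (N_b+1)` grid — producing
taut, cling-film-like interpolating surfaces. A triangle-area cost is
available as an alternative objective.

Real anatomy requires three extra mechanisms:

* **Self-avoidance** — candidate triangles are tested for intersection
  against all previously accepted geometry; an offending move is given
  infinite cost (a *retraction*) and the search re-runs. When a retraction
  budget is exhausted, the search restarts from the next anchor in the
  closest-to-furthest list of vertex pairs. If no anchor succeeds the band
  is returned flagged, never silently.
* **Branching** ("trousers") — contours are grouped across slices by a
  shadow-casting overlap test; when one contour faces several, the many
  are merged into a single polygon by zero-width bridges at the closest
  admissible vertex pairs, then banded normally.
* **Nesting** — annular walls (e.g. gray matter around white matter) are
  matched across slices by containment-depth parity, so outer walls stitch
  to outer walls and inner to inner; terminal slices are capped by ear
  clipping, with nested holes cut by reversed bridges.

For measurement without a mesh, the package also implements the
slice-based analytical approximation (AA). With `S_n`, `P_n` the effective
area and perimeter of slice `n` and `h` the gap:

    A = sum_n sqrt( (S_{n+1} - S_n)^2 + ( h (P_n + P_{n+1}) / 2 )^2 )
    V = sum_n h ( S_n + S_{n+1} + sqrt(S_n S_{n+1}) ) / 3

with nested contours aggregated as `S_n = sum (-1)^depth |S|`,
`P_n = sum P`. Derived metrics: thickness `T = (V_t - V_wm) / A_t`,
gyrification index `GI = A_t / A_e`, and the minimum-gap sampling rule
`gap_min ~ T` (a sulcus spans two cortical walls, `2T`; Nyquist sampling
of that spatial frequency requires a slice gap of at most `T`).

Raw stitched surfaces inherit a terraced, voxel-like jaggedness that
inflates areas. The post-processing pipeline mirrors standard mesh-lab
practice: coherent reorientation → hole closing → simplified isotropic
remeshing → HC-Laplacian smoothing → Taubin smoothing
(`smooth_pipeline()`).

## Worked example

A deeply folded tube phantom (fold half-period 1.9 mm, traced every 1 mm),
reconstructed, audited, smoothed, and then reconstructed again from every
other slice:

```r
library(contourstitch)

ph <- phantom_stack("gyrified_tube", r = 10, n_slices = 14,
                    points_per_contour = 48, gap = 1, amplitude = 2.5,
                    n_folds = 6, axial_freq = pi / 1.9)
mesh <- build_surface(ph$stack)
mesh_audit(mesh)
#> mesh audit: watertight=TRUE oriented=TRUE chi=2 boundary_loops=0 self_intersections=0

smooth <- smooth_pipeline(mesh)
surface_area(mesh);  surface_area(smooth)
#> [1] 2268.49      # raw A_t, mm^2 — inflated by triangulated folds
#> [1] 1650.10      # smooth A_t
enclosed_volume(mesh); enclosed_volume(smooth)
#> [1] 4091.98      # raw V_t, mm^3
#> [1] 4062.59      # volumes barely move (-0.7%)

low <- degrade_resolution(ph$stack, 2)   # gap 2 mm > fold half-period
surface_area(build_surface(low))
#> [1] 1694.09      # undersampled folds: total area drops by a quarter
```

The audit line is the reconstruction contract: closed, coherently
oriented, genus 0, no self-intersections. The area/volume pattern — areas
sensitive to smoothing and slice spacing, volumes nearly invariant — is
the expected behaviour for folded sheets.

The annular-wall phantom exercises the analytical approximation:

```r
ann <- phantom_stack("nested_annulus", r = 8, R = 10, n_slices = 10,
                     points_per_contour = 64, gap = 1)
aa_morphometry(ann$stack)
#>   quantity          AA
#> 1      V_t 2822.893641
#> 2     V_wm 1806.651931
#> 3      A_t  565.259608
#> 5        T    1.797832    # = (R^2 - r^2)/2R for the polygonal shell
#> 8  gap_min    1.797832    # trace at least this finely
```

A command-line wrapper (`inst/cli/contourstitch`) exposes the same
pipeline as subcommands `phantom`, `reconstruct`, `smooth`, `check`,
`morphometry` and `pipeline`, reading cstack-1 JSON stacks and writing
OBJ/PLY/STL meshes and JSON/CSV reports.

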
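Package: contourstitch
Title: Surface Reconstruction and Morphometry from Stacked Planar Contours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds watertight triangle meshes from stacks of closed 2D
    contours traced on parallel slice planes, as produced by manual
    segmentation of anatomical structures in volumetric images. Adjacent
    slices are connected by minimum-total-edge-length ladder triangulations
    with self-intersection avoidance (retraction and restarts from a sorted
    list of anchor vertex pairs), branching contours are merged by shortest
    bridges, and terminal contours are capped by ear clipping. Includes
    mesh post-processing (coherent reorientation, hole closing, simplified
    isotropic remeshing, HC-Laplacian and Taubin smoothing), mesh audits
    (watertightness, Euler characteristic, self-intersection scans), the
    slice-based analytical approximation of lateral area and volume with
    nesting-parity corrections, derived cortical metrics (thickness,
    gyrification index, minimum slice-gap rule), and deterministic phantom
    generators with known analytic geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
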
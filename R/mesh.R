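#' Indexed triangle mesh
#'
#' @param vertices numeric V x 3 matrix of vertex positions in mm.
#' @param faces integer F x 3 matrix of 1-based vertex indices; winding
#'   encodes the face normal (counter-clockwise seen from outside).
#' @param flags optional named list of quality flags (e.g.
#'   `self_avoiding = FALSE` when the band search had to give up).
#' @return an object of class `"trimesh"`.
#' @export
trimesh <- function(vertices, faces, flags = list()) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  dimnames(vertices) <- dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, flags = flags),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  a <- mesh_audit(x, intersections = FALSE)
  cat(sprintf("trimesh: %d vertices, %d faces; watertight: %s; chi = %d\n",
              nrow(x$vertices), nrow(x$faces),
              if (a$watertight) "yes" else "no", a$euler_characteristic))
  if (length(x$flags)) {
    cat("flags:", paste(names(x$flags), unlist(x$flags), sep = "=",
                        collapse = ", "), "\n")
  }
  invisible(x)
}

## Directed edge list (3F x 2) in winding order
.directed_edges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE], faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

## Undirected edge keys for each directed edge
.edge_keys <- function(edges) {
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  paste(lo, hi)
}

#' Total surface area of a mesh
#'
#' @param mesh a [trimesh].
#' @return sum of triangle areas in mm^2.
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!nrow(f)) return(0)
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a closed, coherently oriented mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive when the
#' faces wind outward. Rejects meshes that fail the watertightness audit
#' unless `force = TRUE`.
#'
#' @param mesh a [trimesh].
#' @param force skip the watertightness check (signed value of an open or
#'   incoherent mesh is meaningless).
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(mesh, force = FALSE) {
  if (!force) {
    a <- mesh_audit(mesh, intersections = FALSE)
    if (!a$watertight)
      stop(sprintf("mesh is not watertight (%d boundary loop(s)); volume undefined",
                   a$boundary_loops))
    if (!a$coherently_oriented)
      stop("mesh is not coherently oriented; signed volume undefined")
  }
  .signed_volume(mesh$vertices, mesh$faces)
}

.signed_volume <- function(v, f) {
  if (!nrow(f)) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

## Boundary edges: undirected edges used by exactly one face.
.boundary_edges <- function(faces) {
  de <- .directed_edges(faces)
  keys <- .edge_keys(de)
  tab <- table(keys)
  de[keys %in% names(tab)[tab == 1L], , drop = FALSE]
}

## Count (and optionally return) closed loops formed by boundary edges.
.boundary_loops <- function(faces, return_loops = FALSE) {
  be <- .boundary_edges(faces)
  if (!nrow(be)) return(if (return_loops) list() else 0L)
  nxt <- split(be[, 2], be[, 1])
  used <- rep(FALSE, nrow(be))
  loops <- list()
  # walk directed boundary edges (each boundary vertex of a manifold mesh
  # has one outgoing boundary edge)
  from <- be[, 1]
  for (s in seq_len(nrow(be))) {
    if (used[s]) next
    loop <- integer(0)
    e <- s
    repeat {
      used[e] <- TRUE
      loop <- c(loop, be[e, 1])
      cand <- which(from == be[e, 2] & !used)
      if (!length(cand)) break
      e <- cand[1L]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  if (return_loops) loops else length(loops)
}

#' Structural audit of a triangle mesh
#'
#' Computes edge-incidence watertightness (every undirected edge in exactly
#' two faces), orientation coherence (the two uses traverse the edge in
#' opposite directions), Euler characteristic V - E + F, the number of
#' boundary loops, and (optionally) an exact all-pairs triangle
#' self-intersection count with a bounding-box prefilter. Face pairs
#' sharing a vertex are adjacent by construction and are excluded from the
#' intersection count.
#'
#' @param mesh a [trimesh].
#' @param intersections run the (quadratic, prefiltered) self-intersection
#'   scan.
#' @param tol geometric tolerance in mm for the intersection test.
#' @return a list of class `"mesh_audit"` with fields `watertight`,
#'   `coherently_oriented`, `euler_characteristic`, `boundary_loops`,
#'   `self_intersections` (NA when not scanned).
#' @export
mesh_audit <- function(mesh, intersections = TRUE, tol = 1e-9) {
  v <- mesh$vertices; f <- mesh$faces
  de <- .directed_edges(f)
  keys <- .edge_keys(de)
  tab <- table(keys)
  watertight <- nrow(f) > 0 && all(tab == 2L)
  # orientation coherence: for every undirected edge used exactly twice, the
  # directed versions must be opposite
  dkeys <- paste(de[, 1], de[, 2])
  dtab <- table(dkeys)
  coherent <- all(dtab == 1L) && all(tab <= 2L)
  chi <- nrow(v) - length(tab) + nrow(f)
  loops <- .boundary_loops(f)
  n_int <- NA_integer_
  if (intersections) n_int <- self_intersection_count(mesh, tol = tol)
  structure(list(watertight = watertight,
                 coherently_oriented = coherent,
                 euler_characteristic = as.integer(chi),
                 boundary_loops = as.integer(loops),
                 self_intersections = n_int),
            class = "mesh_audit")
}

#' @export
print.mesh_audit <- function(x, ...) {
  cat(sprintf(paste0("mesh audit: watertight=%s oriented=%s chi=%d ",
                     "boundary_loops=%d self_intersections=%s\n"),
              x$watertight, x$coherently_oriented, x$euler_characteristic,
              x$boundary_loops, as.character(x$self_intersections)))
  invisible(x)
}

#' Count intersecting face pairs of a mesh
#'
#' Exact all-pairs triangle-triangle intersection scan with a bounding-box
#' prefilter and a plane-side prefilter. Face pairs sharing at least one
#' vertex index (adjacent faces, zero-width bridge walls) are excluded:
#' adjacency always touches and is not a violation.
#'
#' @param mesh a [trimesh].
#' @param tol geometric tolerance in mm.
#' @return integer number of properly intersecting face pairs.
#' @export
self_intersection_count <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f)
  if (nf < 2L) return(0L)
  bb <- .face_bboxes(v, f)
  count <- 0L
  for (i in seq_len(nf - 1L)) {
    cand <- .bbox_hits(bb, bb[i, ], tol)
    cand <- cand[cand > i]
    if (!length(cand)) next
    fi <- f[i, ]
    # exclude shared-vertex pairs
    share <- f[cand, 1] %in% fi | f[cand, 2] %in% fi | f[cand, 3] %in% fi
    cand <- cand[!share]
    if (!length(cand)) next
    t1 <- v[fi, , drop = FALSE]
    for (j in cand) {
      if (.tri_tri_intersect(t1, v[f[j, ], , drop = FALSE], tol))
        count <- count + 1L
    }
  }
  count
}

## Does triangle t1 (3x3 coords, with global vertex ids vid1) intersect any
## face of (v, f) within faces `cand`, excluding shared-vertex pairs?
.tri_hits_mesh <- function(t1, vid1, v, f, bb, tol = 1e-9) {
  if (!nrow(f)) return(FALSE)
  b <- c(pmin(t1[1, ], t1[2, ], t1[3, ]), pmax(t1[1, ], t1[2, ], t1[3, ]))
  cand <- .bbox_hits(bb, b, tol)
  if (!length(cand)) return(FALSE)
  share <- f[cand, 1] %in% vid1 | f[cand, 2] %in% vid1 | f[cand, 3] %in% vid1
  cand <- cand[!share]
  for (j in cand) {
    if (.tri_tri_intersect(t1, v[f[j, ], , drop = FALSE], tol)) return(TRUE)
  }
  FALSE
}
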
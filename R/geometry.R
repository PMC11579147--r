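# Internal planar and 3D geometry primitives. Pure R; tolerances are in mm.

.EPS <- 1e-9

## Squared / plain Euclidean distance between 2- or 3-vectors
.dist2 <- function(p, q) sum((p - q)^2)
.dist <- function(p, q) sqrt(sum((p - q)^2))

## Robust-ish 2D orientation: >0 left turn, <0 right turn, 0 collinear
.orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

## Proper intersection of open segments p1-p2 and p3-p4 (shared endpoints do
## not count). Returns NULL or the intersection point.
.seg_intersect <- function(p1, p2, p3, p4, eps = .EPS) {
  d1 <- .orient2d(p3, p4, p1)
  d2 <- .orient2d(p3, p4, p2)
  d3 <- .orient2d(p1, p2, p3)
  d4 <- .orient2d(p1, p2, p4)
  scale <- max(abs(c(p1, p2, p3, p4)), 1)
  tol <- eps * scale * scale
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) {
    t <- d1 / (d1 - d2)
    return(p1 + t * (p2 - p1))
  }
  NULL
}

## Do any edges of polygon A (n x 2) properly cross edges of polygon B?
## With B missing, scans A against itself (non-adjacent edge pairs only).
.poly_edges_cross <- function(a, b = NULL, eps = .EPS) {
  na <- nrow(a)
  ia <- cbind(seq_len(na), c(seq_len(na)[-1], 1L))
  if (is.null(b)) {
    for (i in seq_len(na - 1L)) {
      for (j in (i + 1L):na) {
        # skip adjacent edges (share a vertex, including the wrap pair)
        if (j == i + 1L || (i == 1L && j == na)) next
        if (!is.null(.seg_intersect(a[ia[i, 1], ], a[ia[i, 2], ],
                                    a[ia[j, 1], ], a[ia[j, 2], ], eps)))
          return(TRUE)
      }
    }
    return(FALSE)
  }
  nb <- nrow(b)
  ib <- cbind(seq_len(nb), c(seq_len(nb)[-1], 1L))
  for (i in seq_len(na)) {
    p1 <- a[ia[i, 1], ]; p2 <- a[ia[i, 2], ]
    lo <- pmin(p1, p2); hi <- pmax(p1, p2)
    for (j in seq_len(nb)) {
      q1 <- b[ib[j, 1], ]; q2 <- b[ib[j, 2], ]
      if (max(lo[1] - max(q1[1], q2[1]), lo[2] - max(q1[2], q2[2]),
              min(q1[1], q2[1]) - hi[1], min(q1[2], q2[2]) - hi[2]) > 0) next
      if (!is.null(.seg_intersect(p1, p2, q1, q2, eps))) return(TRUE)
    }
  }
  FALSE
}

## Even-odd point-in-polygon (vectorised over polygon edges).
.point_in_poly <- function(pt, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
  cross <- ((y > pt[2]) != (yj > pt[2])) &
    (pt[1] < (xj - x) * (pt[2] - y) / (yj - y) + x)
  sum(cross, na.rm = TRUE) %% 2 == 1
}

.shoelace <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
  sum(x * yj - xj * y) / 2
}

.poly_perimeter <- function(pts) {
  d <- pts - pts[c(2:nrow(pts), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

## A point strictly inside a simple polygon: centroid of the first valid ear.
.interior_point <- function(pts) {
  n <- nrow(pts)
  if (n == 3L) return(colMeans(pts))
  ccw <- .shoelace(pts) > 0
  for (i in seq_len(n)) {
    ip <- if (i == 1L) n else i - 1L
    in_ <- if (i == n) 1L else i + 1L
    a <- pts[ip, ]; b <- pts[i, ]; c <- pts[in_, ]
    turn <- .orient2d(a, b, c)
    if ((ccw && turn <= 0) || (!ccw && turn >= 0)) next
    # ear must contain no other vertex
    others <- setdiff(seq_len(n), c(ip, i, in_))
    ok <- TRUE
    for (k in others) {
      if (.point_in_tri2d(pts[k, ], a, b, c)) { ok <- FALSE; break }
    }
    if (ok) return((a + b + c) / 3)
  }
  colMeans(pts)  # fallback (convex-ish inputs)
}

.point_in_tri2d <- function(p, a, b, c, tol = 0) {
  d1 <- .orient2d(a, b, p); d2 <- .orient2d(b, c, p); d3 <- .orient2d(c, a, p)
  has_neg <- (d1 < -tol) || (d2 < -tol) || (d3 < -tol)
  has_pos <- (d1 > tol) || (d2 > tol) || (d3 > tol)
  !(has_neg && has_pos)
}

## Ear-clipping triangulation of a simple polygon given as an n x 2 matrix.
## Returns an (n-2) x 3 matrix of vertex indices into `pts`. Degenerate
## (zero-area) ears are clipped without emitting a face.
.ear_clip <- function(pts, eps = 1e-12) {
  n0 <- nrow(pts)
  if (n0 < 3L) stop("cannot triangulate a polygon with fewer than 3 vertices")
  idx <- seq_len(n0)
  ccw <- .shoelace(pts) >= 0
  tris <- matrix(0L, 0L, 3L)
  scale2 <- max(abs(pts))^2 + 1
  guard <- 0L
  while (length(idx) > 3L) {
    n <- length(idx)
    clipped <- FALSE
    for (i in seq_len(n)) {
      ip <- idx[if (i == 1L) n else i - 1L]
      iv <- idx[i]
      in_ <- idx[if (i == n) 1L else i + 1L]
      a <- pts[ip, ]; b <- pts[iv, ]; c <- pts[in_, ]
      turn <- .orient2d(a, b, c)
      if (!ccw) turn <- -turn
      # reflex or collinear vertices are not ears; collinear runs become
      # clippable once a neighbouring convex ear is removed, keeping every
      # boundary vertex in the triangulation (edge-compatible with bands)
      if (turn <= eps * scale2) next
      ok <- TRUE
      for (k in idx) {
        if (k == ip || k == iv || k == in_) next
        # duplicate coordinates (bridged polygons) never block an ear
        if (all(pts[k, ] == a) || all(pts[k, ] == b) || all(pts[k, ] == c)) next
        if (.point_in_tri2d(pts[k, ], a, b, c, tol = eps * scale2)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      tris <- rbind(tris, c(ip, iv, in_))
      idx <- idx[-i]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      # numerical fallback: clip the vertex with the smallest |turn|
      guard <- guard + 1L
      if (guard > n0) stop("ear clipping failed: polygon may not be simple")
      turns <- vapply(seq_along(idx), function(i) {
        n <- length(idx)
        ip <- idx[if (i == 1L) n else i - 1L]
        in_ <- idx[if (i == n) 1L else i + 1L]
        abs(.orient2d(pts[ip, ], pts[idx[i], ], pts[in_, ]))
      }, numeric(1))
      i <- which.min(turns)
      n <- length(idx)
      ip <- idx[if (i == 1L) n else i - 1L]
      in_ <- idx[if (i == n) 1L else i + 1L]
      tris <- rbind(tris, c(ip, idx[i], in_))
      idx <- idx[-i]
    }
  }
  tris <- rbind(tris, idx)
  storage.mode(tris) <- "integer"
  dimnames(tris) <- NULL
  tris
}

## Positive-area overlap of two simple polygons (exact for simple polygons):
## true iff boundaries properly cross, or one polygon's interior point lies
## inside the other. Boundary-only contact is not overlap.
.polys_overlap <- function(a, b, eps = .EPS) {
  # bbox prefilter
  if (min(a[, 1]) > max(b[, 1]) || min(b[, 1]) > max(a[, 1]) ||
      min(a[, 2]) > max(b[, 2]) || min(b[, 2]) > max(a[, 2])) return(FALSE)
  if (.poly_edges_cross(a, b, eps)) return(TRUE)
  # boundaries may cross exactly at shared vertices (no "proper" crossing):
  # any vertex of one polygon strictly inside the other settles it
  if (.any_vertex_strictly_inside(a, b)) return(TRUE)
  if (.any_vertex_strictly_inside(b, a)) return(TRUE)
  if (.point_in_poly(.interior_point(a), b)) return(TRUE)
  if (.point_in_poly(.interior_point(b), a)) return(TRUE)
  FALSE
}

## Is any vertex of `a` strictly inside polygon `b`? Vertices on (or within
## tol of) b's boundary are skipped: the even-odd test is unreliable there
## and boundary contact is not positive-area overlap.
.any_vertex_strictly_inside <- function(a, b, tol = 1e-9) {
  for (k in seq_len(nrow(a))) {
    p <- a[k, ]
    if (.dist_to_boundary(p, b) <= tol * max(abs(b), 1)) next
    if (.point_in_poly(p, b)) return(TRUE)
  }
  FALSE
}

## Minimum distance from point p to the boundary of polygon `poly`
.dist_to_boundary <- function(p, poly) {
  q1 <- poly
  q2 <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
  ex <- q2[, 1] - q1[, 1]; ey <- q2[, 2] - q1[, 2]
  wx <- p[1] - q1[, 1]; wy <- p[2] - q1[, 2]
  len2 <- ex^2 + ey^2
  t <- (wx * ex + wy * ey) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  dx <- wx - t * ex; dy <- wy - t * ey
  sqrt(min(dx^2 + dy^2))
}

## ---- 3D triangle-triangle intersection -----------------------------------

.tri_normal <- function(t) {
  u <- t[2, ] - t[1, ]; v <- t[3, ] - t[1, ]
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Interval of projections of the crossing of triangle t with plane (n, d)
## onto direction dir; helper for the Moller test.
.tri_plane_interval <- function(t, dv, proj) {
  # dv: signed distances of t's vertices to the other plane
  # proj: projections of t's vertices on the intersection line direction
  pos <- dv > 0; neg <- dv < 0
  # vertex on one side alone:
  lone <- if (sum(pos) == 1L) which(pos) else if (sum(neg) == 1L) which(neg)
          else which(dv == 0)
  if (length(lone) != 1L) {
    # one vertex exactly on plane, others on both sides
    lone <- which.min(abs(dv))
  }
  others <- setdiff(1:3, lone)
  t1 <- proj[lone] + (proj[others[1]] - proj[lone]) *
    dv[lone] / (dv[lone] - dv[others[1]])
  t2 <- proj[lone] + (proj[others[2]] - proj[lone]) *
    dv[lone] / (dv[lone] - dv[others[2]])
  sort(c(t1, t2))
}

## 2D triangle overlap with positive area (used for coplanar case)
.tri_tri_2d <- function(a, b, tol) {
  # SAT over the 6 edge normals
  tris <- list(a, b)
  for (t in tris) {
    for (i in 1:3) {
      p <- t[i, ]; q <- t[if (i == 3) 1 else i + 1, ]
      nrm <- c(-(q[2] - p[2]), q[1] - p[1])
      pa <- a %*% nrm; pb <- b %*% nrm
      if (min(pa) >= max(pb) - tol || min(pb) >= max(pa) - tol) return(FALSE)
    }
  }
  TRUE
}

## Positive-measure intersection test for triangles t1, t2 (3 x 3 matrices,
## rows = vertices). Contacts within tol, shared edges and single shared
## points do not count as intersections.
.tri_tri_intersect <- function(t1, t2, tol = 1e-9) {
  n1 <- .tri_normal(t1)
  l1 <- sqrt(sum(n1^2)); if (l1 == 0) return(FALSE)
  n1 <- n1 / l1
  d2 <- as.numeric(t2 %*% n1 - sum(n1 * t1[1, ]))
  if (all(d2 > tol) || all(d2 < -tol)) return(FALSE)
  n2 <- .tri_normal(t2)
  l2 <- sqrt(sum(n2^2)); if (l2 == 0) return(FALSE)
  n2 <- n2 / l2
  d1 <- as.numeric(t1 %*% n2 - sum(n2 * t2[1, ]))
  if (all(d1 > tol) || all(d1 < -tol)) return(FALSE)

  if (all(abs(d2) <= tol) && all(abs(d1) <= tol)) {
    # coplanar: project to dominant axis plane and run 2D SAT
    ax <- which.max(abs(n1))
    keep <- setdiff(1:3, ax)
    return(.tri_tri_2d(t1[, keep, drop = FALSE], t2[, keep, drop = FALSE],
                       tol * max(abs(t1), abs(t2), 1)))
  }
  # clamp near-zero distances so grazing contacts don't register; each
  # triangle must properly straddle the other's plane
  d1[abs(d1) <= tol] <- 0
  d2[abs(d2) <= tol] <- 0
  if (!(any(d1 > 0) && any(d1 < 0))) return(FALSE)
  if (!(any(d2 > 0) && any(d2 < 0))) return(FALSE)
  dir <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
           n1[1] * n2[2] - n1[2] * n2[1])
  ax <- which.max(abs(dir))
  i1 <- .tri_plane_interval(t1, d1, t1[, ax])
  i2 <- .tri_plane_interval(t2, d2, t2[, ax])
  lo <- max(i1[1], i2[1]); hi <- min(i1[2], i2[2])
  span <- hi - lo
  span > tol * max(1, abs(lo), abs(hi))
}

## Axis-aligned bounding boxes for faces of a mesh: F x 6 (xmin..zmax)
.face_bboxes <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  cbind(pmin(v1[, 1], v2[, 1], v3[, 1]), pmin(v1[, 2], v2[, 2], v3[, 2]),
        pmin(v1[, 3], v2[, 3], v3[, 3]), pmax(v1[, 1], v2[, 1], v3[, 1]),
        pmax(v1[, 2], v2[, 2], v3[, 2]), pmax(v1[, 3], v2[, 3], v3[, 3]))
}

## Indices of faces in `bb` whose bbox meets the single bbox `b` (length 6)
.bbox_hits <- function(bb, b, tol = 1e-9) {
  which(bb[, 1] <= b[4] + tol & b[1] <= bb[, 4] + tol &
        bb[, 2] <= b[5] + tol & b[2] <= bb[, 5] + tol &
        bb[, 3] <= b[6] + tol & b[3] <= bb[, 6] + tol)
}
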
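#' Closed planar contour
#'
#' A contour is one closed, traced region-of-interest boundary on a slice
#' plane: an ordered ring of 2D vertices (in mm) at a fixed slice height z.
#' Closure is implicit (the last vertex connects back to the first) and
#' consecutive duplicate points within `dedup_eps` are merged on
#' construction, as tablet tracing routinely produces them.
#'
#' @param points numeric n x 2 matrix of vertex coordinates in mm (or an
#'   n x 3 matrix with a constant third column taken as z).
#' @param z slice height in mm; ignored when `points` has 3 columns.
#' @param label region label, e.g. `"GM"`, `"WM"`, `"exposed"`.
#' @param slice_index non-negative integer index of the slice plane.
#' @param dedup_eps merge distance for consecutive duplicate points, mm.
#' @return an object of class `"contour"`.
#' @export
contour <- function(points, z = 0, label = "ROI", slice_index = 0L,
                    dedup_eps = 1e-6) {
  points <- as.matrix(points)
  if (ncol(points) == 3L) {
    zs <- points[, 3]
    if (diff(range(zs)) > 1e-9)
      stop("contour points must share a single z")
    z <- zs[1]
    points <- points[, 1:2, drop = FALSE]
  }
  if (ncol(points) != 2L) stop("points must be an n x 2 (or n x 3) matrix")
  if (!all(is.finite(points)) || !is.finite(z))
    stop("contour coordinates must be finite")
  storage.mode(points) <- "double"
  # drop consecutive duplicates, including the wrap-around pair
  n <- nrow(points)
  if (n > 1L) {
    d <- sqrt(rowSums((points - points[c(2:n, 1L), , drop = FALSE])^2))
    keep <- d > dedup_eps
    keep <- c(keep[n], keep[-n])  # keep[i]: point i differs from predecessor
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 3L)
    stop("degenerate contour: fewer than 3 distinct points")
  dimnames(points) <- NULL
  structure(list(points = points, z = as.numeric(z),
                 label = as.character(label),
                 slice_index = as.integer(slice_index)),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("contour '%s': %d vertices, z = %g mm, slice %d, area %.4g mm^2\n",
              x$label, nrow(x$points), x$z, x$slice_index,
              abs(signed_area(x))))
  invisible(x)
}

.as_contour_points <- function(x) {
  if (inherits(x, "contour")) x$points else as.matrix(x)
}

#' Signed enclosed area of a contour
#'
#' Shoelace formula. Positive for counter-clockwise traversal viewed from
#' +z, negative for clockwise; the stitching convention stores all contours
#' clockwise (negative).
#'
#' @param x a [contour] or an n x 2 coordinate matrix.
#' @return signed area in mm^2.
#' @export
signed_area <- function(x) {
  pts <- .as_contour_points(x)
  if (nrow(pts) < 3L) stop("degenerate contour: fewer than 3 points")
  .shoelace(pts)
}

#' Perimeter length of a contour
#'
#' Sum of consecutive edge lengths including the closing edge.
#'
#' @inheritParams signed_area
#' @return length in mm.
#' @export
perimeter_length <- function(x) {
  .poly_perimeter(.as_contour_points(x))
}

#' Force clockwise orientation
#'
#' Returns the contour with its vertices ordered clockwise (negative signed
#' area when viewed from +z), reversing the order when needed. Idempotent;
#' the vertex set is unchanged.
#'
#' @param x a [contour].
#' @return a [contour] with `signed_area(x) < 0`.
#' @export
ensure_clockwise <- function(x) {
  a <- signed_area(x)
  if (a == 0) stop("zero-area contour cannot be oriented")
  if (a > 0) x$points <- x$points[rev(seq_len(nrow(x$points))), , drop = FALSE]
  x
}

#' Repair self-crossing contours
#'
#' Noisy tracing occasionally produces bow-tie style self-crossings. Every
#' crossing is resolved at its intersection point, splitting the ring into
#' simple loops; the simple loop of largest absolute area is kept (slivers
#' below `sliver_frac` of the total area are discarded with the rest).
#' Already-simple contours are returned unchanged.
#'
#' @param x a [contour].
#' @param sliver_frac fraction of total area below which split-off loops are
#'   regarded as slivers (documentation of intent; only the largest loop is
#'   kept either way).
#' @return a simple [contour].
#' @export
repair_self_crossings <- function(x, sliver_frac = 1e-4) {
  pts <- x$points
  out <- .largest_simple_loop(pts)
  if (nrow(out) < 3L)
    stop("contour collapsed to fewer than 3 points during crossing repair")
  x$points <- out
  x
}

## Recursively split a ring at its first proper self-crossing and return the
## simple loop with the largest |area|.
.largest_simple_loop <- function(pts, depth = 0L) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  if (depth > 64L) return(pts)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      X <- .seg_intersect(pts[i, ], pts[nxt[i], ], pts[j, ], pts[nxt[j], ])
      if (is.null(X)) next
      loop1 <- rbind(X, pts[(i + 1L):j, , drop = FALSE])
      loop2 <- if (nxt[j] == 1L) rbind(X, pts[1:i, , drop = FALSE])
               else rbind(X, pts[c(nxt[j]:n, 1:i), , drop = FALSE])
      loop1 <- .drop_dup_ring(loop1)
      loop2 <- .drop_dup_ring(loop2)
      l1 <- if (nrow(loop1) >= 3L) .largest_simple_loop(loop1, depth + 1L)
            else loop1
      l2 <- if (nrow(loop2) >= 3L) .largest_simple_loop(loop2, depth + 1L)
            else loop2
      a1 <- if (nrow(l1) >= 3L) abs(.shoelace(l1)) else 0
      a2 <- if (nrow(l2) >= 3L) abs(.shoelace(l2)) else 0
      if (a1 == a2) {  # deterministic tie-break: more vertices, then loop1
        if (nrow(l2) > nrow(l1)) return(l2) else return(l1)
      }
      return(if (a1 >= a2) l1 else l2)
    }
  }
  pts
}

.drop_dup_ring <- function(pts, eps = 1e-9) {
  n <- nrow(pts)
  if (n < 2L) return(pts)
  d <- sqrt(rowSums((pts - pts[c(2:n, 1L), , drop = FALSE])^2))
  keep <- c(d[n], d[-n]) > eps
  pts[keep, , drop = FALSE]
}

#' Merge two disjoint coplanar contours with the shortest bridge
#'
#' Joins two disjoint simple polygons into a single closed polygon by a
#' zero-width bridge at the closest admissible vertex pair: candidate pairs
#' are tried from closest to furthest and a pair is rejected when its bridge
#' segment would cross either input boundary. The two bridge vertices are
#' duplicated so the merged ring stays closed; the result traverses all
#' vertices of both inputs, its perimeter is the sum of the input perimeters
#' plus twice the bridge length, and its absolute area is the sum of the
#' input areas.
#'
#' @param a,b coplanar, disjoint, simple [contour]s with equal orientation.
#' @return a [contour]; attribute `"bridge"` holds the chosen vertex pair
#'   (index in a, index in b) and the bridge length in mm.
#' @export
merge_shortest_bridge <- function(a, b) {
  if (abs(a$z - b$z) > 1e-9) stop("contours to merge must be coplanar")
  pa <- a$points; pb <- b$points
  if (.poly_edges_cross(pa, pb) ||
      .point_in_poly(.interior_point(pa), pb) ||
      .point_in_poly(.interior_point(pb), pa))
    stop("cannot merge overlapping or nested contours: inputs must be disjoint")
  if (sign(.shoelace(pa)) != sign(.shoelace(pb)))
    stop("contours to merge must have equal orientation")
  br <- .shortest_bridge_pair(pa, pb)
  merged <- .bridge_polygons(pa, pb, br[1], br[2])
  out <- a
  out$points <- merged
  attr(out, "bridge") <- list(pair = c(br[1], br[2]),
                              length = .dist(pa[br[1], ], pb[br[2], ]))
  class(out) <- "contour"
  out
}

## Closest vertex pair whose connecting segment crosses neither polygon.
.shortest_bridge_pair <- function(pa, pb) {
  na <- nrow(pa); nb <- nrow(pb)
  dx <- outer(pa[, 1], pb[, 1], "-"); dy <- outer(pa[, 2], pb[, 2], "-")
  d2 <- dx * dx + dy * dy
  ord <- order(d2)
  for (k in ord) {
    i <- (k - 1L) %% na + 1L
    j <- (k - 1L) %/% na + 1L
    if (!.bridge_blocked(pa[i, ], pb[j, ], pa, i) &&
        !.bridge_blocked(pa[i, ], pb[j, ], pb, j)) return(c(i, j))
  }
  stop("no admissible bridge between contours")
}

## Does segment p-q properly cross polygon `poly` (edges not incident to
## vertex `skip` of that polygon)?
.bridge_blocked <- function(p, q, poly, skip) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  for (e in seq_len(n)) {
    if (!is.null(skip) && (e == skip || nxt[e] == skip)) next
    if (!is.null(.seg_intersect(p, q, poly[e, ], poly[nxt[e], ]))) return(TRUE)
  }
  FALSE
}

## Splice polygon b into polygon a at vertices (i, j): zero-width slit.
## reverse_b = TRUE traverses b backwards (used to cut holes into caps).
.bridge_polygons <- function(pa, pb, i, j, reverse_b = FALSE) {
  na <- nrow(pa); nb <- nrow(pb)
  bidx <- if (reverse_b) c(((j - 0:(nb - 1L) - 1L) %% nb) + 1L, j)
          else c(((j + 0:(nb - 1L) - 1L) %% nb) + 1L, j)
  out <- rbind(pa[1:i, , drop = FALSE],
               pb[bidx, , drop = FALSE],
               pa[i:na, , drop = FALSE], deparse.level = 0)
  attr(out, "map") <- c(seq_len(i), rep(NA_integer_, nb + 1L), i:na)
  attr(out, "bmap") <- c(rep(NA_integer_, i), bidx, rep(NA_integer_, na - i + 1L))
  out
}

#' Nesting depth of a contour within its slice plane
#'
#' Number of other contours in the plane strictly containing a
#' representative interior point of `x`. Depth parity drives the
#' algebraic-sign area corrections of the slice aggregates and the
#' wall-to-wall matching of nested contours during stitching.
#'
#' @param x a [contour].
#' @param plane a [slice_plane] containing `x` (and its neighbours).
#' @param others optional list of contours to test against, overriding
#'   `plane`.
#' @return integer depth, 0 for an outermost contour.
#' @export
containment_depth <- function(x, plane = NULL, others = NULL) {
  if (is.null(others)) {
    stopifnot(inherits(plane, "slice_plane"))
    others <- plane$contours
  }
  ip <- .interior_point(x$points)
  ax <- abs(.shoelace(x$points))
  depth <- 0L
  for (o in others) {
    if (identical(o, x)) next
    if (isTRUE(all.equal(o$points, x$points))) next
    if (.poly_edges_cross(x$points, o$points))
      stop("partially overlapping contours in one slice: nesting undefined")
    if (!.point_in_poly(ip, o$points)) next
    # the interior point of x may fall inside a contour nested within x;
    # `o` only counts when it is not itself inside x (larger area decides
    # the mutual case)
    if (.point_in_poly(.interior_point(o$points), x$points) &&
        abs(.shoelace(o$points)) <= ax) next
    depth <- depth + 1L
  }
  depth
}

#' Slice plane
#'
#' All contours of one structure lying on a single slice plane.
#'
#' @param index non-negative integer slice index.
#' @param z slice height in mm.
#' @param contours list of [contour]s, all at height `z`.
#' @return an object of class `"slice_plane"`.
#' @export
slice_plane <- function(index, z, contours = list()) {
  stopifnot(is.numeric(index), is.numeric(z))
  for (ct in contours) {
    stopifnot(inherits(ct, "contour"))
    if (abs(ct$z - z) > 1e-6)
      stop(sprintf("contour z = %g does not match slice z = %g", ct$z, z))
  }
  structure(list(index = as.integer(index), z = as.numeric(z),
                 contours = contours),
            class = "slice_plane")
}

#' Contour stack
#'
#' The full traced representation of one structure: an ordered list of
#' slice planes with a constant inter-slice gap `h` (mm).
#'
#' @param structure structure label, e.g. `"GM"`.
#' @param slices list of [slice_plane]s with strictly increasing index and
#'   z spacing equal to `gap` (within tolerance).
#' @param gap slice spacing h in mm, > 0.
#' @return an object of class `"contour_stack"`.
#' @export
contour_stack <- function(structure, slices, gap) {
  if (!is.numeric(gap) || gap <= 0) stop("gap must be a positive length in mm")
  idx <- vapply(slices, function(s) s$index, integer(1))
  zs <- vapply(slices, function(s) s$z, numeric(1))
  if (length(slices) >= 2L) {
    if (any(diff(idx) <= 0L)) stop("slice indices must be strictly increasing")
    if (any(abs(diff(zs) - gap * diff(idx)) > 1e-6 * max(gap, 1)))
      stop("consecutive slice z values must differ by the gap h")
  }
  base::structure(list(structure = as.character(structure), slices = slices,
                       gap = as.numeric(gap)),
                  class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  nct <- sum(vapply(x$slices, function(s) length(s$contours), integer(1)))
  cat(sprintf("contour_stack '%s': %d slices, %d contours, gap %g mm\n",
              x$structure, length(x$slices), nct, x$gap))
  invisible(x)
}

#' Group contours of adjacent slices by projected overlap
#'
#' Projects the contours of two adjacent slice planes along z and partitions
#' the union into connected components of the positive-overlap relation
#' (bounding-box prefilter, then an exact positive-area overlap test).
#' Groups whose members come from a single slice correspond to appearing or
#' vanishing structures and are capped rather than banded.
#'
#' @param upper,lower adjacent [slice_plane]s.
#' @return list of groups; each group is a list with elements `upper` and
#'   `lower` (lists of contours) and the logical flag `one_sided`.
#' @export
shadow_groups <- function(upper, lower) {
  cu <- upper$contours; cl <- lower$contours
  all_ct <- c(cu, cl)
  side <- c(rep("upper", length(cu)), rep("lower", length(cl)))
  n <- length(all_ct)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (.polys_overlap(all_ct[[i]]$points, all_ct[[j]]$points))
          union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    g <- list(upper = all_ct[members[side[members] == "upper"]],
              lower = all_ct[members[side[members] == "lower"]])
    g$one_sided <- length(g$upper) == 0L || length(g$lower) == 0L
    out[[length(out) + 1L]] <- g
  }
  out
}

## 3D coordinates of a contour's vertices
.contour_points3 <- function(x) {
  cbind(x$points, x$z, deparse.level = 0)
}
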
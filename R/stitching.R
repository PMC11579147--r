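# Minimum-cost ladder stitching between contours of adjacent slices.
#
# A "band" is a triangulated strip between two closed polygons on parallel
# planes in which every triangle uses exactly one polygon edge and two
# spans. Bands are found by dynamic programming on the unrolled
# (Na+1) x (Nb+1) grid anchored at a start vertex pair; self-intersections
# are avoided by marking offending moves with infinite cost (retraction)
# and, when a retraction budget is exhausted, restarting from the next
# anchor in the closest-to-furthest list of vertex pairs.

#' Cost of a span between two stitched vertices
#'
#' The default stitching cost is the total created edge length, yielding
#' taut, cling-film-like interpolating surfaces. `span_cost` is the
#' per-span contribution: the Euclidean distance between a vertex on the
#' upper contour and one on the lower contour. A triangle-area cost is
#' available in [optimal_band] as an alternative objective.
#'
#' @param pa,pb numeric length-3 vectors (mm).
#' @return distance in mm.
#' @export
span_cost <- function(pa, pb) {
  sqrt(sum((pa - pb)^2))
}

## All pairwise distances between rows of two n x 3 matrices
.cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.tri_area3 <- function(a, b, c) {
  u <- b - a; w <- c - a
  sqrt(sum(c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])^2)) / 2
}

## Core DP. A3, B3: vertex coordinate matrices; sa, sb: anchor indices.
## banA/banB: (Na+1) x (Nb+1) logical, TRUE = move into cell banned.
## Returns list(total_cost, moves, tris) with tris as local indices
## (1..Na for contour a, Na+1..Na+Nb for b) in path order.
.band_dp <- function(A3, B3, sa, sb, cost = "length",
                     banA = NULL, banB = NULL) {
  Na <- nrow(A3); Nb <- nrow(B3)
  ra <- ((sa - 1L + 0:Na) %% Na) + 1L
  rb <- ((sb - 1L + 0:Nb) %% Nb) + 1L
  RA <- A3[ra, , drop = FALSE]; RB <- B3[rb, , drop = FALSE]
  S <- .cross_dist(RA, RB)
  if (cost == "length") {
    costA <- S
    costB <- S
  } else if (cost == "area") {
    costA <- matrix(0, Na + 1L, Nb + 1L)
    costB <- matrix(0, Na + 1L, Nb + 1L)
    for (i in 2:(Na + 1L)) for (j in 1:(Nb + 1L))
      costA[i, j] <- .tri_area3(RA[i - 1L, ], RA[i, ], RB[j, ])
    for (i in 1:(Na + 1L)) for (j in 2:(Nb + 1L))
      costB[i, j] <- .tri_area3(RA[i, ], RB[j - 1L, ], RB[j, ])
  } else stop("unknown cost function: ", cost)
  if (is.null(banA)) banA <- matrix(FALSE, Na + 1L, Nb + 1L)
  if (is.null(banB)) banB <- matrix(FALSE, Na + 1L, Nb + 1L)

  M <- matrix(Inf, Na + 1L, Nb + 1L)
  choice <- matrix(0L, Na + 1L, Nb + 1L)  # 1 = advance a, 2 = advance b
  M[1L, 1L] <- 0
  for (j in 2:(Nb + 1L)) {
    if (!banB[1L, j] && is.finite(M[1L, j - 1L])) {
      M[1L, j] <- M[1L, j - 1L] + costB[1L, j]
      choice[1L, j] <- 2L
    }
  }
  for (i in 2:(Na + 1L)) {
    if (!banA[i, 1L] && is.finite(M[i - 1L, 1L])) {
      M[i, 1L] <- M[i - 1L, 1L] + costA[i, 1L]
      choice[i, 1L] <- 1L
    }
    for (j in 2:(Nb + 1L)) {
      va <- if (banA[i, j]) Inf else M[i - 1L, j] + costA[i, j]
      vb <- if (banB[i, j]) Inf else M[i, j - 1L] + costB[i, j]
      if (va < vb) {
        M[i, j] <- va; choice[i, j] <- 1L
      } else if (vb < va) {
        M[i, j] <- vb; choice[i, j] <- 2L
      } else if (is.finite(va)) {
        # deterministic tie-break: advance the contour with more unconsumed
        # vertices; on a second tie advance contour a
        M[i, j] <- va
        choice[i, j] <- if ((Na - i + 1L) >= (Nb - j + 1L)) 1L else 2L
      }
    }
  }
  total <- M[Na + 1L, Nb + 1L]
  if (!is.finite(total))
    return(list(total_cost = Inf, moves = NULL, tris = NULL))
  # backtrack
  nmov <- Na + Nb
  moves <- matrix(0L, nmov, 3L)  # i, j, dir
  tris <- matrix(0L, nmov, 3L)
  i <- Na + 1L; j <- Nb + 1L
  for (k in nmov:1) {
    dir <- choice[i, j]
    moves[k, ] <- c(i, j, dir)
    if (dir == 1L) {
      tris[k, ] <- c(ra[i - 1L], ra[i], Na + rb[j])
      i <- i - 1L
    } else {
      tris[k, ] <- c(ra[i], Na + rb[j - 1L], Na + rb[j])
      j <- j - 1L
    }
  }
  list(total_cost = total, moves = moves, tris = tris)
}

.closest_pair <- function(A3, B3) {
  D <- .cross_dist(A3, B3)
  k <- which.min(D)
  c((k - 1L) %% nrow(A3) + 1L, (k - 1L) %/% nrow(A3) + 1L)
}

#' Minimum-cost ladder triangulation between two contours
#'
#' Dynamic program over the unrolled (Na+1) x (Nb+1) grid anchored at
#' `start_pair`: each step advances one contour by one vertex and emits one
#' triangle, so the band has exactly Na + Nb triangles, uses every contour
#' edge exactly once, and minimises the total cost among all ladder
#' triangulations sharing that anchor. Cost ties are broken
#' deterministically (advance the contour with more unconsumed vertices,
#' then contour `a`).
#'
#' @param a,b [contour]s on adjacent slices (or n x 3 coordinate matrices).
#' @param start_pair integer pair (vertex index in a, vertex index in b)
#'   anchoring the band; default is the globally closest vertex pair.
#' @param cost `"length"` (sum of created span lengths, the default) or
#'   `"area"` (sum of triangle areas).
#' @return an object of class `"band"`: list with `triangles` (local
#'   indices, 1..Na for `a`, Na+1..Na+Nb for `b`), `start_pair`,
#'   `total_cost` (mm for the length cost), `flagged` (FALSE).
#' @export
optimal_band <- function(a, b, start_pair = NULL, cost = "length") {
  A3 <- if (inherits(a, "contour")) .contour_points3(a) else as.matrix(a)
  B3 <- if (inherits(b, "contour")) .contour_points3(b) else as.matrix(b)
  if (nrow(A3) < 3L || nrow(B3) < 3L)
    stop("contours must have at least 3 vertices")
  if (is.null(start_pair)) start_pair <- .closest_pair(A3, B3)
  r <- .band_dp(A3, B3, start_pair[1], start_pair[2], cost)
  structure(list(triangles = r$tris, start_pair = as.integer(start_pair),
                 total_cost = r$total_cost, n_a = nrow(A3), n_b = nrow(B3),
                 retractions = 0L, flagged = FALSE),
            class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("band: %d triangles (%d + %d vertices), cost %.4f%s\n",
              nrow(x$triangles), x$n_a, x$n_b, x$total_cost,
              if (x$flagged) " [FLAGGED: not self-avoiding]" else ""))
  invisible(x)
}

## Map band-local triangle indices to global vertex ids
.band_faces_global <- function(tris, a_ids, b_ids) {
  na <- length(a_ids)
  ids <- c(a_ids, b_ids)
  matrix(ids[tris], ncol = 3L)
}

#' Self-avoiding band between two contours
#'
#' Like [optimal_band], but candidate triangles are tested for intersection
#' against already-accepted geometry (`context`) and against the partial
#' band. A blocked move gets infinite cost and the search re-runs (one
#' "retraction"); when `retraction_budget` is exhausted the search restarts
#' from the next anchor in the closest-to-furthest list of vertex pairs.
#' The first completed intersection-free band is returned. If every anchor
#' fails, the unconstrained minimum-cost band at the closest anchor is
#' returned with `flagged = TRUE` and a warning — never silently.
#'
#' @inheritParams optimal_band
#' @param context a [trimesh] of already-accepted triangles (previous
#'   bands, caps), or NULL.
#' @param a_ids,b_ids optional global vertex ids of the contour vertices in
#'   `context`; used to exclude shared-vertex contacts from the
#'   intersection test. When omitted they are matched by coordinates.
#' @param anchor optional user-supplied anchor pair, honoured as-is (the
#'   search still retracts/flags within it).
#' @param retraction_budget maximum retractions per anchor; default
#'   `10 * (Na + Nb)`.
#' @param max_anchors maximum number of anchors tried; default
#'   `min(Na * Nb, 64)`.
#' @param tol intersection tolerance in mm.
#' @return a `"band"`; `flagged` is TRUE when no intersection-free band was
#'   found.
#' @export
self_avoiding_band <- function(a, b, context = NULL, cost = "length",
                               a_ids = NULL, b_ids = NULL, anchor = NULL,
                               retraction_budget = NULL, max_anchors = NULL,
                               tol = 1e-9) {
  A3 <- if (inherits(a, "contour")) .contour_points3(a) else as.matrix(a)
  B3 <- if (inherits(b, "contour")) .contour_points3(b) else as.matrix(b)
  Na <- nrow(A3); Nb <- nrow(B3)
  if (Na < 3L || Nb < 3L) stop("contours must have at least 3 vertices")
  if (is.null(retraction_budget)) retraction_budget <- 10L * (Na + Nb)
  ctxv <- if (is.null(context)) matrix(0, 0, 3) else context$vertices
  ctxf <- if (is.null(context)) matrix(0L, 0, 3) else context$faces
  if (is.null(a_ids)) a_ids <- .match_vertex_ids(A3, ctxv)
  if (is.null(b_ids)) b_ids <- .match_vertex_ids(B3, ctxv)
  bb <- if (nrow(ctxf)) .face_bboxes(ctxv, ctxf) else NULL
  allv <- rbind(ctxv, A3, B3)
  ga <- ifelse(is.na(a_ids), nrow(ctxv) + seq_len(Na), a_ids)
  gb <- ifelse(is.na(b_ids), nrow(ctxv) + Na + seq_len(Nb), b_ids)

  D <- .cross_dist(A3, B3)
  anchors <- if (!is.null(anchor)) {
    matrix(as.integer(anchor), 1L, 2L)
  } else {
    ord <- order(D)
    if (is.null(max_anchors)) max_anchors <- min(Na * Nb, 64L)
    ord <- ord[seq_len(min(length(ord), max_anchors))]
    cbind((ord - 1L) %% Na + 1L, (ord - 1L) %/% Na + 1L)
  }
  total_retractions <- 0L
  for (ak in seq_len(nrow(anchors))) {
    sa <- anchors[ak, 1]; sb <- anchors[ak, 2]
    banA <- matrix(FALSE, Na + 1L, Nb + 1L)
    banB <- matrix(FALSE, Na + 1L, Nb + 1L)
    retr <- 0L
    repeat {
      r <- .band_dp(A3, B3, sa, sb, cost, banA, banB)
      if (!is.finite(r$total_cost)) break  # anchor infeasible
      bad <- .first_band_violation(r$tris, allv, c(ga, gb), ctxf, bb, tol)
      if (is.na(bad)) {
        return(structure(list(triangles = r$tris,
                              start_pair = c(sa, sb),
                              total_cost = r$total_cost,
                              n_a = Na, n_b = Nb,
                              retractions = total_retractions + retr,
                              flagged = FALSE),
                         class = "band"))
      }
      # retraction: mark the offending move with infinite cost
      mv <- r$moves[bad, ]
      if (mv[3] == 1L) banA[mv[1], mv[2]] <- TRUE else banB[mv[1], mv[2]] <- TRUE
      retr <- retr + 1L
      if (retr > retraction_budget) break
    }
    total_retractions <- total_retractions + retr
  }
  warning("no self-avoiding band found within budget; returning flagged ",
          "minimum-cost band")
  out <- optimal_band(A3, B3, start_pair = anchors[1, ], cost = cost)
  out$flagged <- TRUE
  out$retractions <- total_retractions
  out
}

## Index (in path order) of the first band triangle that intersects the
## context or an earlier band triangle; NA when the band is clean.
.first_band_violation <- function(tris, allv, gids, ctxf, bb, tol) {
  nt <- nrow(tris)
  gtris <- matrix(gids[tris], ncol = 3L)
  # coordinates per triangle
  for (k in seq_len(nt)) {
    vid <- gtris[k, ]
    t1 <- allv[vid, , drop = FALSE]
    if (!is.null(bb) && .tri_hits_mesh(t1, vid, allv, ctxf, bb, tol))
      return(k)
    if (k > 1L) {
      prev <- gtris[seq_len(k - 1L), , drop = FALSE]
      share <- prev[, 1] %in% vid | prev[, 2] %in% vid | prev[, 3] %in% vid
      cand <- which(!share)
      for (j in cand) {
        if (.tri_tri_intersect(t1, allv[prev[j, ], , drop = FALSE], tol))
          return(k)
      }
    }
  }
  NA_integer_
}

.match_vertex_ids <- function(P3, verts) {
  if (!nrow(verts)) return(rep(NA_integer_, nrow(P3)))
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  match(paste(P3[, 1], P3[, 2], P3[, 3]), key)
}

#' Flat triangulation of a contour (cap fill)
#'
#' Ear-clipping triangulation of a simple planar polygon: N - 2 triangles
#' whose union is exactly the polygon interior. Degenerate (zero-area) ears
#' are skipped. The caller fixes the winding; during surface assembly the
#' global outward orientation is set afterwards.
#'
#' @param x a [contour] or an n x 2 coordinate matrix.
#' @return integer (N-2) x 3 matrix of vertex indices into the contour.
#' @export
cap_fill <- function(x) {
  pts <- .as_contour_points(x)
  .ear_clip(pts)
}

#' Stitch one shadow group of contours
#'
#' Resolves one connected group from [shadow_groups]: a side holding
#' several contours is merged into a single polygon by shortest bridges
#' (greedily, closest pair first), a self-avoiding band is built against
#' the other side, and one-sided groups (appearing or vanishing
#' structures) are closed with a flat cap. The zero-width bridge walls
#' share vertex ids, so the local surface is watertight across the saddle.
#'
#' @param upper,lower lists of [contour]s from the two adjacent slices
#'   (either may be empty, not both).
#' @param context optional [trimesh] of already-accepted geometry.
#' @param ... passed to [self_avoiding_band].
#' @return a [trimesh] fragment for the group.
#' @export
stitch_group <- function(upper, lower, context = NULL, ...) {
  if (inherits(upper, "contour")) upper <- list(upper)
  if (inherits(lower, "contour")) lower <- list(lower)
  if (!length(upper) && !length(lower)) stop("empty shadow group")
  env <- .mesh_env(context)
  .stitch_group_env(env, upper, lower, cap_upper = !length(lower),
                    cap_lower = !length(upper), ...)
  nctx <- if (is.null(context)) 0L else nrow(context$faces)
  f <- env$faces[seq_len(env$nf), , drop = FALSE]
  if (nctx > 0L) f <- f[-seq_len(nctx), , drop = FALSE]
  trimesh(env$vertices[seq_len(env$nv), , drop = FALSE], f,
          flags = list(self_avoiding = !env$flagged))
}

## ---- internal growing-mesh environment -----------------------------------

.mesh_env <- function(context = NULL) {
  env <- new.env(parent = emptyenv())
  if (is.null(context)) {
    env$vertices <- matrix(0, 256L, 3L); env$nv <- 0L
    env$faces <- matrix(0L, 256L, 3L); env$nf <- 0L
  } else {
    env$vertices <- context$vertices; env$nv <- nrow(context$vertices)
    env$faces <- context$faces; env$nf <- nrow(context$faces)
  }
  env$bb <- if (env$nf) .face_bboxes(env$vertices, env$faces) else
    matrix(0, 0L, 6L)
  env$flagged <- FALSE
  env$key <- new.env(parent = emptyenv())
  if (env$nv) {
    v <- env$vertices[seq_len(env$nv), , drop = FALSE]
    k <- paste(v[, 1], v[, 2], v[, 3])
    for (i in seq_len(env$nv)) assign(k[i], i, envir = env$key)
  }
  env
}

.env_add_vertices <- function(env, P3) {
  n <- nrow(P3)
  ids <- integer(n)
  for (i in seq_len(n)) {
    k <- paste(P3[i, 1], P3[i, 2], P3[i, 3])
    hit <- get0(k, envir = env$key, inherits = FALSE)
    if (!is.null(hit)) { ids[i] <- hit; next }
    if (env$nv + 1L > nrow(env$vertices))
      env$vertices <- rbind(env$vertices,
                            matrix(0, nrow(env$vertices), 3L))
    env$nv <- env$nv + 1L
    env$vertices[env$nv, ] <- P3[i, ]
    assign(k, env$nv, envir = env$key)
    ids[i] <- env$nv
  }
  ids
}

.env_add_faces <- function(env, faces) {
  if (!nrow(faces)) return(invisible())
  k <- nrow(faces)
  while (env$nf + k > nrow(env$faces))
    env$faces <- rbind(env$faces, matrix(0L, nrow(env$faces), 3L))
  env$faces[env$nf + seq_len(k), ] <- faces
  env$nf <- env$nf + k
  newbb <- .face_bboxes(env$vertices, faces)
  env$bb <- rbind(env$bb[seq_len(min(nrow(env$bb), env$nf - k)), ,
                         drop = FALSE], newbb)
  invisible()
}

.env_mesh <- function(env) {
  list(vertices = env$vertices[seq_len(env$nv), , drop = FALSE],
       faces = env$faces[seq_len(env$nf), , drop = FALSE])
}

## Merge a list of contours on one slice into a single polygon (greedy
## closest pair first). Returns points (n x 2) plus z; the merged ring may
## contain duplicate coordinates at bridge vertices.
.merge_side <- function(contours) {
  while (length(contours) > 1L) {
    n <- length(contours)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D <- .cross_dist(cbind(contours[[i]]$points, 0),
                         cbind(contours[[j]]$points, 0))
        if (min(D) < best[1]) best <- c(min(D), i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merged <- merge_shortest_bridge(contours[[i]], contours[[j]])
    contours <- c(contours[-c(i, j)], list(merged))
  }
  contours[[1L]]
}

## Stitch one shadow group inside a mesh environment.
.stitch_group_env <- function(env, upper, lower, cap_upper = FALSE,
                              cap_lower = FALSE, cost = "length",
                              retraction_budget = NULL, anchor = NULL,
                              max_anchors = NULL, check = TRUE, tol = 1e-9) {
  if (!length(upper) || !length(lower)) {
    # appearing/vanishing structure: cap every contour of the populated side
    side <- if (length(upper)) upper else lower
    .env_cap_regions(env, side)
    return(invisible())
  }
  cu <- if (length(upper) > 1L) .merge_side(upper) else upper[[1L]]
  cl <- if (length(lower) > 1L) .merge_side(lower) else lower[[1L]]
  A3 <- .contour_points3(cu); B3 <- .contour_points3(cl)
  a_ids <- .env_add_vertices(env, A3)
  b_ids <- .env_add_vertices(env, B3)
  ctx <- .env_mesh(env)
  band <- if (check) {
    self_avoiding_band(A3, B3, context = trimesh(ctx$vertices, ctx$faces),
                       cost = cost, a_ids = a_ids, b_ids = b_ids,
                       anchor = anchor, retraction_budget = retraction_budget,
                       max_anchors = max_anchors, tol = tol)
  } else {
    optimal_band(A3, B3, start_pair = anchor, cost = cost)
  }
  if (band$flagged) env$flagged <- TRUE
  .env_add_faces(env, .band_faces_global(band$triangles, a_ids, b_ids))
  invisible()
}

## Cap the planar regions bounded by a set of nested contours on one slice:
## every even-depth contour together with its direct odd-depth children
## forms one region; holes are cut by reversed zero-width bridges, then the
## region is ear-clipped.
.env_cap_regions <- function(env, contours) {
  if (inherits(contours, "contour")) contours <- list(contours)
  n <- length(contours)
  depth <- vapply(contours, containment_depth, integer(1), others = contours)
  for (i in which(depth %% 2L == 0L)) {
    outer <- contours[[i]]
    kids <- which(depth == depth[i] + 1L &
                    vapply(contours, function(c2)
                      .point_in_poly(.interior_point(c2$points),
                                     outer$points), logical(1)))
    pts <- outer$points
    gids <- .env_add_vertices(env, .contour_points3(outer))
    same_orient <- sign(.shoelace(outer$points))
    for (k in kids) {
      hole <- contours[[k]]
      hid <- .env_add_vertices(env, .contour_points3(hole))
      # bridge at the closest admissible vertex pair between current ring
      # and the hole
      br <- .shortest_bridge_pair(pts, hole$points)
      rev_hole <- sign(.shoelace(hole$points)) == same_orient
      merged <- .bridge_polygons(pts, hole$points, br[1], br[2],
                                 reverse_b = rev_hole)
      amap <- attr(merged, "map"); bmap <- attr(merged, "bmap")
      newg <- integer(nrow(merged))
      newg[!is.na(amap)] <- gids[amap[!is.na(amap)]]
      newg[!is.na(bmap)] <- hid[bmap[!is.na(bmap)]]
      pts <- merged
      gids <- newg
    }
    tris <- .ear_clip(pts)
    .env_add_faces(env, matrix(gids[tris], ncol = 3L))
  }
  invisible()
}

#' Reconstruct a closed surface from a contour stack
#'
#' The full stitching pipeline: for every pair of adjacent slices the
#' contours are grouped by projected overlap ([shadow_groups]), nested
#' contours within a group are matched wall-to-wall by containment-depth
#' parity, branch groups are merged by shortest bridges, and each match is
#' banded with the self-avoiding minimum-edge-length triangulation. First-
#' and last-slice contours (and contours of appearing/vanishing structures)
#' are capped by ear clipping, with nested holes cut by reversed bridges.
#' The assembled mesh is reoriented coherently with outward normals
#' (positive enclosed volume per connected component). The construction is
#' deterministic: identical stacks give identical meshes.
#'
#' @param stack a [contour_stack] (contours are normalised to simple,
#'   clockwise rings on the way in).
#' @param cost stitching cost, `"length"` or `"area"`.
#' @param check test candidate triangles against accepted geometry and
#'   retract/restart on intersections (the self-avoidance condition).
#' @param retraction_budget,max_anchors,tol passed to
#'   [self_avoiding_band].
#' @return a [trimesh]; `flags$self_avoiding` is FALSE when any band had to
#'   be emitted flagged.
#' @export
build_surface <- function(stack, cost = "length", check = TRUE,
                          retraction_budget = NULL, max_anchors = NULL,
                          tol = 1e-9) {
  stopifnot(inherits(stack, "contour_stack"))
  ns <- length(stack$slices)
  if (ns < 2L) stop("at least 2 slices are required for a reconstruction")
  slices <- lapply(stack$slices, function(sp) {
    sp$contours <- lapply(sp$contours, function(ct)
      ensure_clockwise(repair_self_crossings(ct)))
    sp
  })
  env <- .mesh_env(NULL)
  # caps on the first slice
  if (length(slices[[1L]]$contours))
    .env_cap_regions(env, slices[[1L]]$contours)
  for (s in seq_len(ns - 1L)) {
    up <- slices[[s]]; lo <- slices[[s + 1L]]
    groups <- shadow_groups(up, lo)
    for (g in groups) {
      # match nested walls by containment-depth parity within the group
      du <- vapply(g$upper, containment_depth, integer(1), others = up$contours)
      dl <- vapply(g$lower, containment_depth, integer(1), others = lo$contours)
      for (par in unique(c(du %% 2L, dl %% 2L))) {
        gu <- g$upper[du %% 2L == par]
        gl <- g$lower[dl %% 2L == par]
        if (!length(gu) && !length(gl)) next
        if (!length(gl)) {
          # vanishes going down: cap on the upper slice (only if it does not
          # continue upward -- i.e. always cap here; the region ends at this
          # interface)
          .env_cap_regions(env, gu)
        } else if (!length(gu)) {
          .env_cap_regions(env, gl)
        } else {
          .stitch_group_env(env, gu, gl, cost = cost, check = check,
                            retraction_budget = retraction_budget,
                            max_anchors = max_anchors, tol = tol)
        }
      }
    }
  }
  if (length(slices[[ns]]$contours))
    .env_cap_regions(env, slices[[ns]]$contours)
  m <- .env_mesh(env)
  mesh <- trimesh(m$vertices, m$faces,
                  flags = list(self_avoiding = !env$flagged,
                               structure = stack$structure))
  reorient_coherently(mesh)
}
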
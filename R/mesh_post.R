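# Post-processing pipeline for reconstructed surfaces: coherent
# reorientation, hole closing, simplified isotropic remeshing, HC-Laplacian
# and Taubin smoothing. The prescribed order of the full pipeline is
# reorient -> close holes -> remesh -> HC -> Taubin (see smooth_pipeline).

#' Reorient all faces coherently
#'
#' Breadth-first walk over the face adjacency graph flipping windings so
#' every manifold edge is traversed in opposite directions by its two
#' faces; each connected component is then globally flipped, if necessary,
#' so its signed volume is non-negative (outward normals).
#'
#' @param mesh a [trimesh].
#' @return a [trimesh] with coherent, outward orientation.
#' @export
reorient_coherently <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  de <- .directed_edges(f)
  keys <- .edge_keys(de)
  face_of_edge <- rep(seq_len(nf), 3L)
  ord <- split(seq_along(keys), keys)
  # adjacency via manifold edges only (exactly 2 uses)
  adj <- vector("list", nf)
  for (es in ord) {
    if (length(es) != 2L) next
    f1 <- face_of_edge[es[1]]; f2 <- face_of_edge[es[2]]
    if (f1 == f2) next
    adj[[f1]] <- c(adj[[f1]], f2)
    adj[[f2]] <- c(adj[[f2]], f1)
  }
  flip <- rep(FALSE, nf)
  seen <- rep(FALSE, nf)
  comp <- rep(0L, nf)
  ncomp <- 0L
  for (s in seq_len(nf)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s; seen[s] <- TRUE; comp[s] <- ncomp
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[cur]]) {
        same <- .same_edge_direction(f, cur, nb)
        # coherent iff effective directions oppose
        want_flip <- xor(same, flip[cur])
        if (!seen[nb]) {
          seen[nb] <- TRUE
          comp[nb] <- ncomp
          flip[nb] <- want_flip
          queue <- c(queue, nb)
        }
      }
    }
  }
  f2 <- f
  f2[flip, ] <- f2[flip, c(1L, 3L, 2L), drop = FALSE]
  # outward sense per component
  for (cc in seq_len(ncomp)) {
    sel <- comp == cc
    if (.signed_volume(mesh$vertices, f2[sel, , drop = FALSE]) < 0)
      f2[sel, ] <- f2[sel, c(1L, 3L, 2L), drop = FALSE]
  }
  trimesh(mesh$vertices, f2, mesh$flags)
}

## Do faces i and j traverse a shared undirected edge in the same direction?
.same_edge_direction <- function(f, i, j) {
  ei <- rbind(f[i, c(1, 2)], f[i, c(2, 3)], f[i, c(3, 1)])
  ej <- rbind(f[j, c(1, 2)], f[j, c(2, 3)], f[j, c(3, 1)])
  for (a in 1:3) {
    for (b in 1:3) {
      if (ei[a, 1] == ej[b, 1] && ei[a, 2] == ej[b, 2]) return(TRUE)
      if (ei[a, 1] == ej[b, 2] && ei[a, 2] == ej[b, 1]) return(FALSE)
    }
  }
  NA
}

#' Close boundary holes of a mesh
#'
#' Finds boundary loops (edges used by exactly one face), and fills every
#' loop whose perimeter does not exceed `max_boundary_len` with a flat
#' ear-clipped patch in the loop's best-fit plane. By default all loops are
#' filled, since a stitched reconstruction is meant to be closed.
#'
#' @param mesh a [trimesh].
#' @param max_boundary_len fill only loops with perimeter at most this
#'   value (mm); default `Inf` fills everything.
#' @return a [trimesh].
#' @export
close_holes <- function(mesh, max_boundary_len = Inf) {
  loops <- .boundary_loops(mesh$faces, return_loops = TRUE)
  if (!length(loops)) return(mesh)
  v <- mesh$vertices
  newf <- list()
  for (loop in loops) {
    if (length(loop) < 3L) next
    P <- v[loop, , drop = FALSE]
    per <- sum(sqrt(rowSums((P - P[c(2:nrow(P), 1L), , drop = FALSE])^2)))
    if (per > max_boundary_len) next
    ctr <- colMeans(P)
    Q <- sweep(P, 2L, ctr)
    sv <- svd(Q)
    P2 <- Q %*% sv$v[, 1:2, drop = FALSE]
    tris <- .ear_clip(P2)
    newf[[length(newf) + 1L]] <- matrix(loop[tris], ncol = 3L)
  }
  if (!length(newf)) return(mesh)
  out <- trimesh(v, rbind(mesh$faces, do.call(rbind, newf)), mesh$flags)
  reorient_coherently(out)
}

## vertex adjacency list from faces
.vertex_adjacency <- function(faces, nv) {
  de <- .directed_edges(faces)
  lo <- pmin(de[, 1], de[, 2]); hi <- pmax(de[, 1], de[, 2])
  e <- unique(cbind(lo, hi))
  adj <- vector("list", nv)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  adj
}

.boundary_vertices <- function(faces) {
  be <- .boundary_edges(faces)
  unique(as.vector(be))
}

## uniform-weight Laplacian displacement: average neighbour - vertex
.laplacian_displacement <- function(v, adj, fixed) {
  out <- matrix(0, nrow(v), 3L)
  for (i in seq_len(nrow(v))) {
    if (fixed[i] || is.null(adj[[i]])) next
    out[i, ] <- colMeans(v[adj[[i]], , drop = FALSE]) - v[i, ]
  }
  out
}

#' HC-Laplacian smoothing (Vollmer et al. scheme)
#'
#' A Laplacian smoothing step followed by a "humphrey classes" correction
#' that pushes vertices back toward their pre-smoothing (and, weighted by
#' `alpha`, original) positions, largely cancelling the volume shrinkage of
#' plain Laplacian flow.
#'
#' @param mesh a [trimesh].
#' @param iterations number of HC iterations.
#' @param alpha weight of the original positions in the correction
#'   reference (0..1).
#' @param beta weight of a vertex's own correction versus its neighbours'
#'   mean correction (0..1).
#' @return a smoothed [trimesh]; connectivity is unchanged.
#' @export
hc_laplacian_smooth <- function(mesh, iterations = 1L, alpha = 0.0,
                                beta = 0.5) {
  if (iterations < 1L) return(mesh)
  v0 <- mesh$vertices
  v <- v0
  adj <- .vertex_adjacency(mesh$faces, nrow(v))
  fixed <- rep(FALSE, nrow(v))
  bv <- .boundary_vertices(mesh$faces)
  if (length(bv)) fixed[bv] <- TRUE
  for (it in seq_len(iterations)) {
    q <- v
    lap <- .laplacian_displacement(v, adj, fixed)
    p <- v + lap
    b <- p - (alpha * v0 + (1 - alpha) * q)
    corr <- matrix(0, nrow(v), 3L)
    for (i in seq_len(nrow(v))) {
      if (fixed[i] || is.null(adj[[i]])) next
      corr[i, ] <- beta * b[i, ] +
        (1 - beta) * colMeans(b[adj[[i]], , drop = FALSE])
    }
    v <- p - corr
  }
  trimesh(v, mesh$faces, mesh$flags)
}

#' Taubin smoothing
#'
#' Alternating shrink (`lambda > 0`) and inflate (`mu < 0`) uniform-weight
#' Laplacian steps; the signal-processing band-pass choice
#' `lambda = 0.5, mu = -0.53` smooths high-frequency jaggedness with little
#' net shrinkage.
#'
#' @param mesh a [trimesh].
#' @param iterations number of lambda/mu pairs.
#' @param lambda positive smoothing factor.
#' @param mu negative inflation factor.
#' @return a smoothed [trimesh]; connectivity is unchanged.
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  if (iterations < 1L) return(mesh)
  v <- mesh$vertices
  adj <- .vertex_adjacency(mesh$faces, nrow(v))
  fixed <- rep(FALSE, nrow(v))
  bv <- .boundary_vertices(mesh$faces)
  if (length(bv)) fixed[bv] <- TRUE
  for (it in seq_len(iterations)) {
    v <- v + lambda * .laplacian_displacement(v, adj, fixed)
    v <- v + mu * .laplacian_displacement(v, adj, fixed)
  }
  trimesh(v, mesh$faces, mesh$flags)
}

#' Simplified isotropic remeshing
#'
#' A simplified incremental remesher: per iteration, edges longer than
#' 4/3 of the target length are split at their midpoint, edges shorter
#' than 4/5 of the target are collapsed (when topologically safe), edges
#' are flipped toward regular vertex valence, and interior vertices are
#' relaxed tangentially (the Laplacian displacement projected onto the
#' tangent plane of the vertex normal, so the surface is not inflated or
#' deflated). Unlike full-featured remeshers there is no projection back
#' onto the input surface, which keeps area and volume drift small but not
#' zero.
#'
#' @param mesh a [trimesh].
#' @param target_edge target edge length in mm, or `"auto"` (median input
#'   edge length).
#' @param iterations number of split/collapse/flip/relax sweeps.
#' @return a remeshed [trimesh]; flag `remeshed = "simplified"` records the
#'   variant.
#' @export
isotropic_remesh <- function(mesh, target_edge = "auto", iterations = 3L) {
  v <- mesh$vertices; f <- mesh$faces
  if (identical(target_edge, "auto")) {
    de <- .directed_edges(f)
    len <- sqrt(rowSums((v[de[, 1], , drop = FALSE] -
                           v[de[, 2], , drop = FALSE])^2))
    target_edge <- stats::median(len)
  }
  hi <- 4 / 3 * target_edge
  lo <- 4 / 5 * target_edge
  for (it in seq_len(iterations)) {
    sp <- .remesh_split(v, f, hi)
    v <- sp$v; f <- sp$f
    cl <- .remesh_collapse(v, f, lo)
    v <- cl$v; f <- cl$f
    f <- .remesh_flip(v, f)
    v <- .remesh_relax(v, f)
  }
  flags <- mesh$flags
  flags$remeshed <- "simplified"
  trimesh(v, f, flags)
}

## split all edges longer than `hi` at their midpoints (1-to-4 style
## per-face subdivision patterns driven by which edges are long)
.remesh_split <- function(v, f, hi) {
  de <- .directed_edges(f)
  lo_ <- pmin(de[, 1], de[, 2]); hi_ <- pmax(de[, 1], de[, 2])
  ekey <- paste(lo_, hi_)
  len <- sqrt(rowSums((v[de[, 1], , drop = FALSE] -
                         v[de[, 2], , drop = FALSE])^2))
  long <- unique(ekey[len > hi])
  if (!length(long)) return(list(v = v, f = f))
  # midpoint vertex per long edge
  mid_id <- new.env(parent = emptyenv())
  for (k in long) {
    ij <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    v <- rbind(v, (v[ij[1], ] + v[ij[2], ]) / 2)
    assign(k, nrow(v), envir = mid_id)
  }
  newf <- vector("list", nrow(f))
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
    m_ab <- get0(paste(min(a, b), max(a, b)), envir = mid_id)
    m_bc <- get0(paste(min(b, c_), max(b, c_)), envir = mid_id)
    m_ca <- get0(paste(min(c_, a), max(c_, a)), envir = mid_id)
    k <- sum(!is.null(m_ab), !is.null(m_bc), !is.null(m_ca))
    if (k == 0L) {
      newf[[t]] <- c(a, b, c_)
    } else if (k == 3L) {
      newf[[t]] <- rbind(c(a, m_ab, m_ca), c(m_ab, b, m_bc),
                         c(m_ca, m_bc, c_), c(m_ab, m_bc, m_ca))
    } else if (k == 1L) {
      if (!is.null(m_ab)) newf[[t]] <- rbind(c(a, m_ab, c_), c(m_ab, b, c_))
      else if (!is.null(m_bc)) newf[[t]] <- rbind(c(b, m_bc, a), c(m_bc, c_, a))
      else newf[[t]] <- rbind(c(c_, m_ca, b), c(m_ca, a, b))
    } else {
      # two split edges: rotate so the unsplit edge is (a, b)
      if (is.null(m_ab)) {
        # edges bc and ca split
        newf[[t]] <- rbind(c(b, m_bc, m_ca), c(b, m_ca, a), c(m_bc, c_, m_ca))
      } else if (is.null(m_bc)) {
        newf[[t]] <- rbind(c(c_, m_ca, m_ab), c(c_, m_ab, b), c(m_ca, a, m_ab))
      } else {
        newf[[t]] <- rbind(c(a, m_ab, m_bc), c(a, m_bc, c_), c(m_ab, b, m_bc))
      }
    }
  }
  f2 <- do.call(rbind, newf)
  storage.mode(f2) <- "integer"
  list(v = v, f = f2)
}

## Feature (crease/corner) vertices: incident face normals spread wider
## than `angle` degrees. Moving these cuts corners (e.g. cap rims), so the
## collapse and relaxation passes leave them in place.
.feature_vertices <- function(v, f, angle = 40) {
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  l <- sqrt(rowSums(fn^2)); l[l == 0] <- 1
  fn <- fn / l
  inc <- vector("list", nrow(v))
  for (k in 1:3) {
    for (t_ in seq_len(nrow(f))) inc[[f[t_, k]]] <- c(inc[[f[t_, k]]], t_)
  }
  thr <- cos(angle * pi / 180)
  out <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    ids <- inc[[i]]
    if (length(ids) < 2L) next
    mn <- colSums(fn[ids, , drop = FALSE])
    mn <- mn / max(sqrt(sum(mn^2)), 1e-300)
    if (min(fn[ids, , drop = FALSE] %*% mn) < thr) out[i] <- TRUE
  }
  out
}

## collapse edges shorter than `lo` to their midpoint when the link
## condition holds; one conservative pass (touched vertices are skipped)
.remesh_collapse <- function(v, f, lo) {
  de <- .directed_edges(f)
  l_ <- pmin(de[, 1], de[, 2]); h_ <- pmax(de[, 1], de[, 2])
  eu <- unique(cbind(l_, h_))
  len <- sqrt(rowSums((v[eu[, 1], , drop = FALSE] -
                         v[eu[, 2], , drop = FALSE])^2))
  ord <- order(len)
  adj <- .vertex_adjacency(f, nrow(v))
  bv <- .feature_vertices(v, f)
  b <- .boundary_vertices(f)
  if (length(b)) bv[b] <- TRUE
  touched <- rep(FALSE, nrow(v))
  remap <- seq_len(nrow(v))
  for (k in ord) {
    if (len[k] >= lo) break
    i <- eu[k, 1]; j <- eu[k, 2]
    if (touched[i] || touched[j] || bv[i] || bv[j]) next
    common <- intersect(adj[[i]], adj[[j]])
    if (length(common) != 2L) next  # link condition (manifold interior edge)
    mid <- (v[i, ] + v[j, ]) / 2
    v[i, ] <- mid
    remap[j] <- i
    touched[c(i, j, adj[[i]], adj[[j]])] <- TRUE
  }
  f2 <- matrix(remap[f], ncol = 3L)
  deg <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 3] == f2[, 1]
  f2 <- f2[!deg, , drop = FALSE]
  # drop now-unreferenced vertices
  used <- sort(unique(as.vector(f2)))
  lookup <- integer(nrow(v)); lookup[used] <- seq_along(used)
  list(v = v[used, , drop = FALSE],
       f = matrix(lookup[f2], ncol = 3L))
}

## flip interior edges when it reduces deviation from valence 6
.remesh_flip <- function(v, f) {
  nf <- nrow(f)
  de <- .directed_edges(f)
  keys <- .edge_keys(de)
  face_of_edge <- rep(seq_len(nf), 3L)
  slot_of_edge <- rep(1:3, each = nf)
  groups <- split(seq_along(keys), keys)
  val <- tabulate(f, nbins = nrow(v))
  bv <- rep(FALSE, nrow(v))
  b <- .boundary_vertices(f)
  if (length(b)) bv[b] <- TRUE
  fdone <- rep(FALSE, nf)
  gadj <- .vertex_adjacency(f, nrow(v))
  for (g in groups) {
    if (length(g) != 2L) next
    f1 <- face_of_edge[g[1]]; f2 <- face_of_edge[g[2]]
    if (f1 == f2 || fdone[f1] || fdone[f2]) next
    shared <- intersect(f[f1, ], f[f2, ])
    if (length(shared) != 2L) next
    o1 <- setdiff(f[f1, ], shared); o2 <- setdiff(f[f2, ], shared)
    if (length(o1) != 1L || length(o2) != 1L) next
    if (any(bv[shared])) next
    a <- shared[1]; b2 <- shared[2]
    dev <- function(vals) sum((vals - 6L)^2)
    before <- dev(val[c(a, b2, o1, o2)])
    after <- dev(val[c(a, b2, o1, o2)] + c(-1L, -1L, 1L, 1L))
    if (after >= before) next
    # geometric guard: only flip when the two triangles are nearly coplanar
    n1 <- .tri_normal(v[f[f1, ], , drop = FALSE])
    n2 <- .tri_normal(v[f[f2, ], , drop = FALSE])
    cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)) + 1e-300)
    if (is.na(cosang) || cosang < 0.965) next
    # flipped edge must not already exist elsewhere in the mesh
    if (o2 %in% gadj[[o1]]) next
    # rebuild the two faces preserving orientation of face f1
    i1 <- which(f[f1, ] == o1)
    nxt <- f[f1, c(2, 3, 1)][i1]   # vertex after o1 in f1's winding
    f[f1, ] <- c(o1, nxt, o2)
    f[f2, ] <- c(o2, setdiff(shared, nxt), o1)
    val[c(a, b2)] <- val[c(a, b2)] - 1L
    val[c(o1, o2)] <- val[c(o1, o2)] + 1L
    gadj[[o1]] <- c(gadj[[o1]], o2)
    gadj[[o2]] <- c(gadj[[o2]], o1)
    fdone[c(f1, f2)] <- TRUE
  }
  f
}

## tangential relaxation: Laplacian displacement minus its normal component
.remesh_relax <- function(v, f) {
  adj <- .vertex_adjacency(f, nrow(v))
  fixed <- .feature_vertices(v, f)
  b <- .boundary_vertices(f)
  if (length(b)) fixed[b] <- TRUE
  nrm <- .vertex_normals(v, f)
  lap <- .laplacian_displacement(v, adj, fixed)
  dot <- rowSums(lap * nrm)
  v + (lap - nrm * dot)
}

.vertex_normals <- function(v, f) {
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nrm <- matrix(0, nrow(v), 3L)
  for (col in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, col], f[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      nrm[idx, col] <- nrm[idx, col] + acc
    }
  }
  l <- sqrt(rowSums(nrm^2))
  l[l == 0] <- 1
  nrm / l
}

#' Full smoothing pipeline
#'
#' The fixed post-processing order applied to raw reconstructions:
#' coherent reorientation, hole closing, simplified isotropic remeshing,
#' HC-Laplacian smoothing, then Taubin smoothing.
#'
#' @param mesh a [trimesh].
#' @param target_edge remeshing target edge length (mm) or `"auto"`.
#' @param remesh_iterations sweeps of the remesher.
#' @param hc_iterations,hc_alpha,hc_beta HC-Laplacian parameters.
#' @param taubin_iterations,lambda,mu Taubin parameters.
#' @return a smoothed, closed [trimesh].
#' @export
smooth_pipeline <- function(mesh, target_edge = "auto",
                            remesh_iterations = 2L, hc_iterations = 1L,
                            hc_alpha = 0.0, hc_beta = 0.5,
                            taubin_iterations = 10L, lambda = 0.5,
                            mu = -0.53) {
  m <- reorient_coherently(mesh)
  m <- close_holes(m)
  m <- isotropic_remesh(m, target_edge = target_edge,
                        iterations = remesh_iterations)
  m <- hc_laplacian_smooth(m, iterations = hc_iterations, alpha = hc_alpha,
                           beta = hc_beta)
  taubin_smooth(m, iterations = taubin_iterations, lambda = lambda, mu = mu)
}
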
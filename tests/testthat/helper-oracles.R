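# Shared fixtures and independent oracles used across the suite.

## Monte-Carlo polygon area by rejection sampling (oracle for shoelace)
mc_polygon_area <- function(pts, n = 1e6, seed = 7) {
  set.seed(seed)
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  px <- stats::runif(n, xr[1], xr[2])
  py <- stats::runif(n, yr[1], yr[2])
  inside <- vapply(seq_len(n), function(i)
    contourstitch:::.point_in_poly(c(px[i], py[i]), pts), logical(1))
  mean(inside) * diff(xr) * diff(yr)
}

## Exhaustive O(N^2) segment-pair crossing scan (oracle for simplicity)
has_self_crossing <- function(pts) {
  contourstitch:::.poly_edges_cross(pts)
}

## Brute-force minimum ladder-band cost over all C(Na+Nb, Na) monotone
## paths with a fixed anchor (oracle for the DP)
brute_band_cost <- function(A3, B3, sa, sb) {
  Na <- nrow(A3); Nb <- nrow(B3)
  ra <- ((sa - 1 + 0:Na) %% Na) + 1
  rb <- ((sb - 1 + 0:Nb) %% Nb) + 1
  S <- contourstitch:::.cross_dist(A3[ra, , drop = FALSE],
                                   B3[rb, , drop = FALSE])
  combs <- utils::combn(Na + Nb, Na)
  best <- Inf
  for (c_ in seq_len(ncol(combs))) {
    steps <- rep(2L, Na + Nb); steps[combs[, c_]] <- 1L
    i <- 1L; j <- 1L; cost <- 0
    for (s in steps) {
      if (s == 1L) i <- i + 1L else j <- j + 1L
      cost <- cost + S[i, j]
    }
    if (cost < best) best <- cost
  }
  best
}

## Random simple polygon: radial star with jittered radii (always simple)
random_star_polygon <- function(n, rmin = 2, rmax = 5) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(r * cos(th), r * sin(th))
}

## Brute-force overlap-graph connected components (oracle for shadow_groups)
brute_shadow_components <- function(contours) {
  n <- length(contours)
  ids <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (contourstitch:::.polys_overlap(contours[[i]]$points,
                                           contours[[j]]$points) &&
            ids[i] != ids[j]) {
          ids[ids == ids[j]] <- ids[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ids
}

## U-shaped traced contour (deep central sulcus), optionally rotated
u_contour <- function(z, rot = 0, slice_index = 0) {
  pts <- rbind(c(-4, -4), c(4, -4), c(4, 4), c(2, 4), c(2, -2),
               c(-2, -2), c(-2, 4), c(-4, 4))
  if (rot != 0) {
    Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    pts <- pts %*% t(Rm)
  }
  ensure_clockwise(contour(pts, z = z, slice_index = slice_index))
}

## square contour helper
square_contour <- function(side = 1, z = 0, center = c(0, 0),
                           slice_index = 0, ccw = TRUE) {
  s <- side / 2
  pts <- rbind(c(-s, -s), c(s, -s), c(s, s), c(-s, s))
  if (!ccw) pts <- pts[4:1, ]
  pts <- sweep(pts, 2, -center)
  contour(pts, z = z, slice_index = slice_index)
}

ngon_area <- function(r, np) contourstitch:::.ngon_area(r, np)
ngon_perimeter <- function(r, np) contourstitch:::.ngon_perimeter(r, np)
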
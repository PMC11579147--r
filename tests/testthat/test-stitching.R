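test_that("span cost is the Euclidean distance and symmetric", {
  expect_equal(span_cost(c(0, 0, 0), c(0, 0, 1)), 1.0)
  expect_equal(span_cost(c(0, 0, 0), c(3, 4, 0)), 5.0)
  a <- c(1.3, -2.2, 0.5); b <- c(-0.1, 4, 2)
  expect_equal(span_cost(a, b), span_cost(b, a))
})

test_that("optimal band on matched unit squares is the prism band", {
  a <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), z = 0)
  b <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), z = 1,
               slice_index = 1)
  bd <- optimal_band(a, b, start_pair = c(1, 1))
  expect_equal(nrow(bd$triangles), 8L)
  expect_equal(bd$total_cost, 4 * 1 + 4 * sqrt(2), tolerance = 1e-12)
  # lateral area of the band equals the prism wall area
  V <- rbind(cbind(a$points, 0), cbind(b$points, 1))
  m <- trimesh(V, matrix(c(bd$triangles), ncol = 3))
  expect_equal(surface_area(m), 4.0, tolerance = 1e-12)
})

test_that("band edge accounting is a perfect cover", {
  set.seed(13)
  for (rep in 1:5) {
    Na <- sample(4:9, 1); Nb <- sample(4:9, 1)
    a <- ensure_clockwise(contour(random_star_polygon(Na), z = 0))
    b <- ensure_clockwise(contour(random_star_polygon(Nb), z = 1,
                                  slice_index = 1))
    bd <- optimal_band(a, b)
    expect_equal(nrow(bd$triangles), Na + Nb)
    # every contour edge of a and b used exactly once
    edge_count <- function(tris, n, offset) {
      cnt <- integer(n)
      for (k in seq_len(nrow(tris))) {
        t_ <- sort(tris[k, ] - offset)
        onc <- t_[t_ >= 1 & t_ <= n]
        if (length(onc) == 2L) {
          lo <- onc[1]; hi <- onc[2]
          if (hi - lo == 1L || (lo == 1L && hi == n)) {
            e <- if (hi - lo == 1L) lo else n
            cnt[e] <- cnt[e] + 1L
          }
        }
      }
      cnt
    }
    expect_true(all(edge_count(bd$triangles, Na, 0L) == 1L))
    bt <- bd$triangles
    bt[bt <= Na] <- NA
    cntb <- edge_count(ifelse(is.na(bt), -1000L, bt), Nb, Na)
    expect_true(all(cntb == 1L))
    # every vertex used at least once
    expect_setequal(unique(c(bd$triangles)), 1:(Na + Nb))
  }
})

test_that("DP band cost equals exhaustive enumeration (oracle, fixed anchors)", {
  set.seed(99)
  for (rep in 1:25) {
    Na <- sample(3:7, 1); Nb <- sample(3:7, 1)
    A3 <- cbind(random_star_polygon(Na), 0)
    B3 <- cbind(random_star_polygon(Nb), 1)
    sa <- sample(Na, 1); sb <- sample(Nb, 1)
    dp <- contourstitch:::.band_dp(A3, B3, sa, sb, "length")$total_cost
    expect_equal(dp, brute_band_cost(A3, B3, sa, sb), tolerance = 1e-9)
  }
})

test_that("pentagon over hexagon matches the exhaustive minimum", {
  A3 <- cbind(contourstitch:::.circle_points(3, 5, phase = 0.3), 0)
  B3 <- cbind(contourstitch:::.circle_points(4, 6), 1)
  bd <- optimal_band(A3, B3, start_pair = c(1, 1))
  expect_equal(bd$total_cost, brute_band_cost(A3, B3, 1, 1),
               tolerance = 1e-9)
})

test_that("cylinder band cost and area follow the closed form", {
  np <- 16; r <- 5; h <- 2
  A3 <- cbind(contourstitch:::.circle_points(r, np), 0)
  B3 <- cbind(contourstitch:::.circle_points(r, np), h)
  bd <- optimal_band(A3, B3, start_pair = c(1, 1))
  edge <- 2 * r * sin(pi / np)
  diag <- sqrt(edge^2 + h^2)
  expect_equal(bd$total_cost, np * h + np * diag, tolerance = 1e-9)
  V <- rbind(A3, B3)
  m <- trimesh(V, matrix(c(bd$triangles), ncol = 3))
  expect_equal(surface_area(m), ngon_perimeter(r, np) * h, tolerance = 1e-9)
})

test_that("self-avoiding band equals the optimal band on convex stacks", {
  np <- 24
  a <- contour(contourstitch:::.circle_points(8, np), z = 0)
  b <- contour(contourstitch:::.circle_points(8, np), z = 1, slice_index = 1)
  sab <- self_avoiding_band(a, b)
  ob <- optimal_band(a, b)
  expect_false(sab$flagged)
  expect_equal(sab$retractions, 0L)
  expect_equal(sab$total_cost, ob$total_cost)
  expect_identical(sab$triangles, ob$triangles)
})

test_that("a blocking obstacle forces retraction and a clean detour", {
  a <- ensure_clockwise(contour(rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
                                z = 0))
  th <- pi / 4
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  b <- ensure_clockwise(contour(rbind(c(-5, -5), c(5, -5), c(5, 5),
                                      c(-5, 5)) %*% t(Rm), z = 1,
                                slice_index = 1))
  ob <- optimal_band(a, b)
  A3 <- contourstitch:::.contour_points3(a)
  B3 <- contourstitch:::.contour_points3(b)
  V <- rbind(A3, B3)
  tri <- V[ob$triangles[3, ], ]
  ctr <- colMeans(tri)
  blk <- sweep(sweep(tri, 2, ctr) * 0.6, 2, ctr, "+")
  ctx <- trimesh(blk, matrix(1:3, 1))
  sab <- self_avoiding_band(a, b, context = ctx)
  expect_false(sab$flagged)
  expect_gt(sab$retractions, 0L)
  expect_gte(sab$total_cost, ob$total_cost)
  # completed band passes a full intersection scan against the obstacle
  allv <- rbind(ctx$vertices, V)
  f2 <- matrix(contourstitch:::.band_faces_global(
    sab$triangles, 3 + 1:4, 3 + 4 + 1:4), ncol = 3)
  mm <- trimesh(allv, rbind(ctx$faces, f2))
  expect_equal(self_intersection_count(mm), 0L)
})

test_that("a user-supplied anchor is honoured", {
  a <- contour(contourstitch:::.circle_points(5, 12), z = 0)
  b <- contour(contourstitch:::.circle_points(5, 12), z = 1, slice_index = 1)
  sab <- self_avoiding_band(a, b, anchor = c(4, 7))
  ob <- optimal_band(a, b, start_pair = c(4, 7))
  expect_equal(sab$start_pair, c(4L, 7L))
  expect_equal(sab$total_cost, ob$total_cost)
})

test_that("an impossible configuration returns a flagged band with a warning", {
  a <- contour(contourstitch:::.circle_points(2, 6), z = 0)
  b <- contour(contourstitch:::.circle_points(2, 6), z = 1, slice_index = 1)
  # a plate right between the slices blocks every possible band
  plate <- trimesh(rbind(c(-50, -50, 0.5), c(50, -50, 0.5), c(0, 100, 0.5)),
                   matrix(1:3, 1))
  expect_warning(sab <- self_avoiding_band(a, b, context = plate,
                                           max_anchors = 4,
                                           retraction_budget = 10),
                 "flagged")
  expect_true(sab$flagged)
})

test_that("cap fill covers exactly the polygon interior", {
  hexa <- contour(contourstitch:::.circle_points(4, 6))
  tris <- cap_fill(hexa)
  expect_equal(nrow(tris), 4L)
  area <- sum(vapply(seq_len(nrow(tris)), function(i)
    abs(contourstitch:::.shoelace(hexa$points[tris[i, ], ])), numeric(1)))
  expect_equal(area, abs(signed_area(hexa)), tolerance = 1e-12)

  # identity on a triangle
  tri <- contour(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(nrow(cap_fill(tri)), 1L)

  # concave L-shape: triangles cover exactly the L (point sampling oracle)
  L <- contour(rbind(c(0, 0), c(4, 0), c(4, 1), c(1, 1), c(1, 3), c(0, 3)))
  ltris <- cap_fill(L)
  expect_equal(nrow(ltris), 4L)
  set.seed(17)
  px <- stats::runif(1e5, 0, 4); py <- stats::runif(1e5, 0, 3)
  in_poly <- vapply(seq_along(px), function(i)
    contourstitch:::.point_in_poly(c(px[i], py[i]), L$points), logical(1))
  in_tris <- rep(FALSE, length(px))
  for (k in seq_len(nrow(ltris))) {
    t_ <- L$points[ltris[k, ], ]
    hit <- vapply(seq_along(px), function(i)
      contourstitch:::.point_in_tri2d(c(px[i], py[i]), t_[1, ], t_[2, ],
                                      t_[3, ]), logical(1))
    in_tris <- in_tris | hit
  }
  # exclude points within a hair of any triangle boundary (ties at edges)
  off_edge <- abs(px - 1) > 1e-3 & abs(py - 1) > 1e-3
  expect_equal(sum(in_poly[off_edge] != in_tris[off_edge]), 0L)
})

test_that("stitch groups resolve 1-1, trousers, and cap-only cases", {
  circ <- function(r, c2, z, i) contour(
    contourstitch:::.circle_points(r, 16, center = c2), z = z,
    slice_index = i)
  # 1-to-1: plain band, Na+Nb faces
  f1 <- stitch_group(list(circ(5, c(0, 0), 0, 0)),
                     list(circ(5, c(0.5, 0), 1, 1)))
  expect_equal(nrow(f1$faces), 32L)
  # trousers: 1 above, 2 below; local surface is watertight up to its rims
  up <- circ(6, c(0, 0), 0, 0)
  lo1 <- circ(2.4, c(-3, 0), 1, 1); lo2 <- circ(2.4, c(3, 0), 1, 1)
  f2 <- stitch_group(list(up), list(lo1, lo2))
  de <- contourstitch:::.directed_edges(f2$faces)
  tab <- table(contourstitch:::.edge_keys(de))
  expect_true(all(tab <= 2L))
  # every non-rim edge is in exactly 2 faces; rim edges lie on the contours
  expect_equal(sum(tab == 1L), 16L + 16L + 16L)
  # cap-only group (structure ends)
  f3 <- stitch_group(list(circ(5, c(0, 0), 0, 0)), list())
  expect_equal(nrow(f3$faces), 14L)
})

test_that("build_surface on a 2-slice square stack is a closed box", {
  stk <- contour_stack("box", list(
    slice_plane(0, 0, list(square_contour(2, z = 0))),
    slice_plane(1, 1.5, list(square_contour(2, z = 1.5, slice_index = 1)))),
    gap = 1.5)
  m <- build_surface(stk)
  aud <- mesh_audit(m)
  expect_true(aud$watertight)
  expect_true(aud$coherently_oriented)
  expect_equal(aud$euler_characteristic, 2L)
  expect_equal(aud$self_intersections, 0L)
  expect_equal(enclosed_volume(m), 4 * 1.5, tolerance = 1e-12)
  expect_equal(surface_area(m), 2 * 4 + 4 * 2 * 1.5, tolerance = 1e-12)
})

test_that("build_surface rejects stacks with fewer than 2 slices", {
  stk <- contour_stack("one", list(slice_plane(0, 0, list(square_contour(1)))),
                       gap = 1)
  expect_error(build_surface(stk), "2 slices")
})

test_that("cylinder stack reconstructs to the analytic values within 1%", {
  ph <- phantom_stack("cylinder", r = 10, n_slices = 20,
                      points_per_contour = 64, gap = 1)
  m <- build_surface(ph$stack)
  aud <- mesh_audit(m, intersections = FALSE)
  expect_true(aud$watertight)
  expect_equal(aud$euler_characteristic, 2L)
  expect_lt(abs(enclosed_volume(m) - ph$reference$volume) /
              ph$reference$volume, 0.01)
  expect_lt(abs(surface_area(m) - ph$reference$area_total) /
              ph$reference$area_total, 0.01)
})

test_that("torus stack (branching) reconstructs with Euler characteristic 0", {
  ph <- phantom_stack("torus", r = 3, R = 10, n_slices = 16,
                      points_per_contour = 24)
  m <- build_surface(ph$stack)
  aud <- mesh_audit(m)
  expect_true(aud$watertight)
  expect_true(aud$coherently_oriented)
  expect_equal(aud$euler_characteristic, 0L)
  expect_equal(aud$self_intersections, 0L)
})

test_that("reconstruction is deterministic: identical input, identical mesh", {
  ph <- phantom_stack("gyrified_tube", r = 8, n_slices = 8,
                      points_per_contour = 32, gap = 1, amplitude = 1.5,
                      n_folds = 5, axial_freq = 0.9)
  m1 <- build_surface(ph$stack)
  m2 <- build_surface(phantom_stack("gyrified_tube", r = 8, n_slices = 8,
                                    points_per_contour = 32, gap = 1,
                                    amplitude = 1.5, n_folds = 5,
                                    axial_freq = 0.9)$stack)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})
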
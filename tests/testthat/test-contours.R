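test_that("signed area follows the orientation convention and matches Monte-Carlo", {
  sq <- square_contour(1, center = c(0.5, 0.5))
  expect_equal(signed_area(sq), 1.0)
  rev_sq <- contour(sq$points[4:1, ], z = 0)
  expect_equal(signed_area(rev_sq), -1.0)

  set.seed(11)
  poly <- random_star_polygon(12)
  a_mc <- mc_polygon_area(poly, n = 1e6)
  expect_lt(abs(abs(contourstitch:::.shoelace(poly)) - a_mc) / a_mc, 0.005)
})

test_that("degenerate contours are rejected", {
  expect_error(contour(rbind(c(0, 0), c(1, 0))), "degenerate")
  expect_error(contour(rbind(c(0, 0), c(0, 0), c(1e-9, 0))), "degenerate")
})

test_that("consecutive duplicate points are merged on construction", {
  ct <- contour(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(1, 1), c(0, 1)))
  expect_equal(nrow(ct$points), 4L)
  expect_equal(abs(signed_area(ct)), 1.0)
})

test_that("perimeter length is exact on closed forms and rotation-invariant", {
  expect_equal(perimeter_length(square_contour(1)), 4.0)
  hex <- contour(contourstitch:::.circle_points(10, 64))
  expect_equal(perimeter_length(hex), 64 * 2 * 10 * sin(pi / 64))
  # cyclic relabeling leaves the perimeter unchanged
  pts <- hex$points
  rolled <- contour(pts[c(17:64, 1:16), ])
  expect_equal(perimeter_length(rolled), perimeter_length(hex))
})

test_that("area and perimeter are invariant under rigid in-plane motion", {
  set.seed(3)
  poly <- random_star_polygon(20)
  a0 <- abs(contourstitch:::.shoelace(poly))
  p0 <- contourstitch:::.poly_perimeter(poly)
  th <- 1.234
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(poly %*% t(Rm), 2, c(-17.5, 42.1), "+")
  expect_equal(abs(contourstitch:::.shoelace(moved)), a0, tolerance = 1e-9)
  expect_equal(contourstitch:::.poly_perimeter(moved), p0, tolerance = 1e-9)
})

test_that("ensure_clockwise flips CCW rings, is idempotent, preserves |area|", {
  ccw <- square_contour(2)
  cw <- ensure_clockwise(ccw)
  expect_lt(signed_area(cw), 0)
  expect_identical(ensure_clockwise(cw), cw)
  expect_equal(abs(signed_area(cw)), abs(signed_area(ccw)))
  expect_setequal(asplit(cw$points, 1), asplit(ccw$points, 1))

  set.seed(5)
  poly <- random_star_polygon(20)
  out <- ensure_clockwise(contour(poly))
  expect_lt(signed_area(out), 0)
  expect_equal(abs(signed_area(out)), abs(contourstitch:::.shoelace(poly)))

  flat <- rbind(c(0, 0), c(1, 0), c(2, 0), c(1, 0.0))
  expect_error(ensure_clockwise(contour(flat)), "zero-area")
})

test_that("self-crossing repair keeps the dominant simple loop", {
  # asymmetric bow-tie: crossing resolved, larger lobe kept, output simple
  bt <- contour(rbind(c(0, 0), c(3, 3), c(3, 0), c(0, 2)))
  out <- repair_self_crossings(bt)
  expect_false(has_self_crossing(out$points))
  expect_gt(abs(signed_area(out)), 0)

  # simple input untouched
  sq <- square_contour(1)
  expect_identical(repair_self_crossings(sq)$points, sq$points)

  # two independent crossings: zigzag strip; output passes the O(N^2) scan
  zz <- contour(rbind(c(0, 0), c(10, 0), c(10, 3), c(7, 3), c(7, -1),
                      c(4, -1), c(4, 3), c(0, 3)))
  out2 <- repair_self_crossings(zz)
  expect_false(has_self_crossing(out2$points))
})

test_that("shortest-bridge merge is minimal, complete and area/perimeter additive", {
  a <- ensure_clockwise(square_contour(1, center = c(0.5, 0.5)))
  b <- ensure_clockwise(square_contour(1, center = c(2.5, 0.5)))
  m <- merge_shortest_bridge(a, b)
  br <- attr(m, "bridge")
  # brute force over all vertex pairs confirms the minimal bridge length
  D <- contourstitch:::.cross_dist(cbind(a$points, 0), cbind(b$points, 0))
  expect_equal(br$length, min(D))
  expect_equal(br$length, 1.0)
  expect_equal(nrow(m$points), 4 + 4 + 2)
  expect_equal(perimeter_length(m),
               perimeter_length(a) + perimeter_length(b) + 2 * br$length,
               tolerance = 1e-9)
  expect_equal(abs(signed_area(m)),
               abs(signed_area(a)) + abs(signed_area(b)), tolerance = 1e-9)
  expect_false(has_self_crossing(m$points))

  # mirror-symmetric inputs: bridge equals the symmetric gap
  c1 <- ensure_clockwise(square_contour(2, center = c(-2, 0)))
  c2 <- ensure_clockwise(square_contour(2, center = c(2, 0)))
  expect_equal(attr(merge_shortest_bridge(c1, c2), "bridge")$length, 2.0)

  expect_error(merge_shortest_bridge(a, a), "disjoint")
})

test_that("bridges that would cross a contour are skipped", {
  # C-shape whose globally closest vertex pair to the enclosed square lies
  # across the C's thin right arm: that bridge would cross the arm and must
  # be skipped for the closest admissible pair
  cshape <- ensure_clockwise(contour(rbind(
    c(0, 0), c(10, 0), c(10, 5), c(10, 10), c(0, 10), c(0, 9), c(9, 9),
    c(9, 1), c(0, 1))))
  sq <- ensure_clockwise(square_contour(0.5, center = c(8.5, 5)))
  # blocked minimal pair: square's right side to the outer vertex (10, 5)
  D <- contourstitch:::.cross_dist(cbind(cshape$points, 0),
                                   cbind(sq$points, 0))
  m <- merge_shortest_bridge(cshape, sq)
  br <- attr(m, "bridge")
  expect_gt(br$length, min(D))  # the naive closest pair was rejected
  expect_false(has_self_crossing(m$points))
  expect_equal(abs(signed_area(m)),
               abs(signed_area(cshape)) + abs(signed_area(sq)),
               tolerance = 1e-9)
})

test_that("containment depth counts strict nesting and rejects partial overlap", {
  lone <- square_contour(1)
  pl <- slice_plane(0, 0, list(lone))
  expect_equal(containment_depth(lone, pl), 0L)

  outer <- contour(contourstitch:::.circle_points(10, 32))
  inner <- contour(contourstitch:::.circle_points(4, 32))
  pl2 <- slice_plane(0, 0, list(outer, inner))
  expect_equal(containment_depth(inner, pl2), 1L)
  expect_equal(containment_depth(outer, pl2), 0L)

  s0 <- square_contour(9); s1 <- square_contour(5); s2 <- square_contour(2)
  pl3 <- slice_plane(0, 0, list(s0, s1, s2))
  expect_equal(vapply(list(s0, s1, s2), containment_depth, integer(1),
                      plane = pl3), 0:2)

  bad <- square_contour(5, center = c(4, 0))
  expect_error(containment_depth(bad, slice_plane(0, 0, list(s0, bad))),
               "overlap")
})

test_that("shadow groups partition contours by projected overlap", {
  circ <- function(r, c2, z, i) contour(contourstitch:::.circle_points(r, 24, center = c2),
                                        z = z, slice_index = i)
  up <- slice_plane(0, 0, list(circ(5, c(0, 0), 0, 0)))
  lo <- slice_plane(1, 1, list(circ(5, c(1, 0), 1, 1)))
  g <- shadow_groups(up, lo)
  expect_length(g, 1L)
  expect_false(g[[1]]$one_sided)

  # branch: one circle above two disjoint overlapping circles below
  lo2 <- slice_plane(1, 1, list(circ(2, c(-2.5, 0), 1, 1),
                                circ(2, c(2.5, 0), 1, 1)))
  g2 <- shadow_groups(up, lo2)
  expect_length(g2, 1L)
  expect_length(g2[[1]]$lower, 2L)

  # two far-apart pairs -> two groups; compare with brute-force components
  up3 <- slice_plane(0, 0, list(circ(2, c(-10, 0), 0, 0), circ(2, c(10, 0), 0, 0)))
  lo3 <- slice_plane(1, 1, list(circ(2, c(-10, 1), 1, 1), circ(2, c(10, 1), 1, 1)))
  g3 <- shadow_groups(up3, lo3)
  expect_length(g3, 2L)
  all_ct <- c(up3$contours, lo3$contours)
  expect_length(unique(brute_shadow_components(all_ct)), 2L)

  # vanishing structure is flagged one-sided
  lo4 <- slice_plane(1, 1, list(circ(2, c(40, 0), 1, 1)))
  g4 <- shadow_groups(up, lo4)
  expect_length(g4, 2L)
  expect_true(all(vapply(g4, `[[`, logical(1), "one_sided")))
})

test_that("shadow grouping agrees with brute force on random slices", {
  set.seed(21)
  for (rep in 1:8) {
    n_up <- sample(1:4, 1); n_lo <- sample(1:4, 1)
    mk <- function(k, z, i) {
      lapply(seq_len(k), function(j)
        contour(sweep(random_star_polygon(12, 1, 3), 2,
                      stats::runif(2, -8, 8), "+"), z = z, slice_index = i))
    }
    up <- mk(n_up, 0, 0); lo <- mk(n_lo, 1, 1)
    # grouping requires disjoint-or-nested within a slice; overlap across
    # slices is what is grouped, so any contour arrangement is legal input
    g <- shadow_groups(slice_plane(0, 0, up), slice_plane(1, 1, lo))
    sizes <- sort(vapply(g, function(gg) length(gg$upper) + length(gg$lower),
                         integer(1)))
    ids <- brute_shadow_components(c(up, lo))
    expect_equal(sizes, sort(as.integer(table(ids))))
    expect_equal(sum(sizes), n_up + n_lo)
  }
})
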
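# Deterministic synthetic contour stacks with known analytic geometry and
# topology. These replace manual segmentations as the test and demo
# substrate: every phantom ships with its polygon-corrected reference
# values (inscribed N-gon closed forms, not smooth-limit values), so
# tolerance budgets isolate stitching error from discretisation error.

## inscribed N-gon area / perimeter for a circle of radius r
.ngon_area <- function(r, np) np * r^2 * sin(2 * pi / np) / 2
.ngon_perimeter <- function(r, np) 2 * np * r * sin(pi / np)

.circle_points <- function(r, np, phase = 0, center = c(0, 0)) {
  th <- phase + 2 * pi * (seq_len(np) - 1L) / np
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic contour stack with known geometry
#'
#' Deterministic phantom generators used for validation and demos:
#' \describe{
#'   \item{cylinder}{one circle per slice, radius `r`.}
#'   \item{frustum}{radius linear from `r` to `r2` across slices; the
#'     conical-frustum volume rule is exact for it.}
#'   \item{sphere}{circles of radius `sqrt(r^2 - z^2)`.}
#'   \item{torus}{tube radius `r` around a circle of radius `R` whose axis
#'     is parallel to the slice planes, so mid slices hold two contours and
#'     polar slices one — exercising branch ("trousers") handling.}
#'   \item{nested_annulus}{outer circle `R` (label `GM`) and nested inner
#'     circle `r` (label `WM`) per slice — exercising nesting-parity
#'     aggregation and depth-matched wall stitching.}
#'   \item{gyrified_tube}{circle modulated as
#'     `r(theta, z) = r + amplitude * sin(n_folds * theta) * sin(axial_freq * z)`
#'     — deep folds for the self-avoidance and minimum-gap analyses.}
#'   \item{terraced_cylinder}{cylinder whose vertices are snapped to a
#'     voxel-like grid of pitch `step`, reproducing the ladder-like jagged
#'     raw surface that smoothing is meant to remove.}
#'   \item{knot_case}{two slices with a deep narrow sulcus starting on
#'     opposing sides — the adversarial inconsistent-segmentation scenario.}
#' }
#'
#' @param kind phantom kind, see Details.
#' @param r primary radius (tube/cylinder/inner radius), mm.
#' @param R secondary radius (torus ring, annulus outer), mm.
#' @param r2 final radius for `frustum`.
#' @param n_slices number of slices.
#' @param points_per_contour vertices per generated contour.
#' @param gap slice spacing h in mm (ignored for `sphere`/`torus`, where it
#'   follows from the geometry and `n_slices`).
#' @param amplitude,n_folds,axial_freq gyrification parameters (mm, count,
#'   rad/mm).
#' @param step voxel pitch for `terraced_cylinder`, mm.
#' @param sulcus_depth,sulcus_width knot-case sulcus geometry (mm, rad).
#' @param jitter_sd optional Gaussian vertex jitter (mm); 0 keeps the
#'   phantom exactly deterministic.
#' @param seed RNG seed used only when `jitter_sd > 0`.
#' @param label contour label for single-label phantoms.
#' @return an object of class `"phantom"`: list with `stack` (a
#'   [contour_stack]) and `reference` (named list of analytic values:
#'   areas/volumes in mm^2/mm^3 where defined, `euler_characteristic`).
#' @export
phantom_stack <- function(kind = c("cylinder", "frustum", "sphere", "torus",
                                   "nested_annulus", "gyrified_tube",
                                   "terraced_cylinder", "knot_case"),
                          r = 10, R = 10, r2 = 5, n_slices = 20L,
                          points_per_contour = 64L, gap = 1,
                          amplitude = 2, n_folds = 6, axial_freq = 1,
                          step = 1, sulcus_depth = NULL,
                          sulcus_width = 0.35, jitter_sd = 0, seed = NULL,
                          label = "GM") {
  kind <- match.arg(kind)
  np <- as.integer(points_per_contour)
  n <- as.integer(n_slices)
  if (np < 3L || n < 2L) stop("need at least 3 points and 2 slices")
  h <- gap
  slices <- list()
  ref <- list(kind = kind)
  add_slice <- function(i, z, pts_list, labels = label) {
    cts <- mapply(function(p, lb) contour(p, z = z, label = lb,
                                          slice_index = i),
                  pts_list,
                  if (length(labels) == 1L) rep(labels, length(pts_list))
                  else labels,
                  SIMPLIFY = FALSE)
    slices[[length(slices) + 1L]] <<- slice_plane(i, z, cts)
  }
  switch(kind,
    cylinder = {
      for (i in seq_len(n) - 1L)
        add_slice(i, i * h, list(.circle_points(r, np)))
      H <- (n - 1L) * h
      ref$area_lateral <- .ngon_perimeter(r, np) * H
      ref$area_total <- ref$area_lateral + 2 * .ngon_area(r, np)
      ref$volume <- .ngon_area(r, np) * H
      ref$euler_characteristic <- 2L
    },
    frustum = {
      radii <- seq(r, r2, length.out = n)
      for (i in seq_len(n) - 1L)
        add_slice(i, i * h, list(.circle_points(radii[i + 1L], np)))
      S <- .ngon_area(radii, np)
      i <- seq_len(n - 1L)
      ref$volume <- sum(h * (S[i] + S[i + 1L] + sqrt(S[i] * S[i + 1L])) / 3)
      ref$euler_characteristic <- 2L
    },
    sphere = {
      h <- 2 * r / n
      zs <- -r + (seq_len(n) - 0.5) * h
      for (i in seq_len(n) - 1L)
        add_slice(i, zs[i + 1L], list(.circle_points(
          sqrt(max(r^2 - zs[i + 1L]^2, 1e-9)), np)))
      ref$volume_smooth <- 4 / 3 * pi * r^3
      ref$area_smooth <- 4 * pi * r^2
      ref$euler_characteristic <- 2L
    },
    torus = {
      if (R <= r) stop("torus needs R > r")
      zmax <- R + 0.5 * r
      h <- 2 * zmax / (n - 1L)
      zs <- -zmax + (seq_len(n) - 1L) * h
      for (i in seq_len(n) - 1L) {
        z0 <- zs[i + 1L]
        cts <- .torus_slice(z0, R, r, np)
        add_slice(i, z0, cts)
      }
      ref$volume_smooth <- 2 * pi^2 * R * r^2
      ref$euler_characteristic <- 0L
    },
    nested_annulus = {
      if (R <= r) stop("nested_annulus needs outer R > inner r")
      for (i in seq_len(n) - 1L)
        add_slice(i, i * h,
                  list(.circle_points(R, np), .circle_points(r, np)),
                  labels = c("GM", "WM"))
      H <- (n - 1L) * h
      ref$volume_wall <- (.ngon_area(R, np) - .ngon_area(r, np)) * H
      ref$volume_outer <- .ngon_area(R, np) * H
      ref$volume_inner <- .ngon_area(r, np) * H
      ref$area_outer_lateral <- .ngon_perimeter(R, np) * H
      ref$thickness <- (.ngon_area(R, np) - .ngon_area(r, np)) /
        .ngon_perimeter(R, np)
      ref$euler_characteristic <- 0L
    },
    gyrified_tube = {
      th <- 2 * pi * (seq_len(np) - 1L) / np
      for (i in seq_len(n) - 1L) {
        z <- i * h
        rad <- r + amplitude * sin(n_folds * th) * sin(axial_freq * z)
        add_slice(i, z, list(cbind(rad * cos(th), rad * sin(th))))
      }
      ref$base_radius <- r
      ref$fold_half_period <- pi / axial_freq
      ref$euler_characteristic <- 2L
    },
    terraced_cylinder = {
      # voxel-like artifact: vertices snapped to a grid of pitch `step`,
      # with the radius jumping by step/2 between odd and even slices the
      # way a voxelized boundary jumps between voxel columns
      for (i in seq_len(n) - 1L) {
        pts <- .circle_points(r + (i %% 2L) * step / 2, np)
        pts <- round(pts / (step / 2)) * (step / 2)
        add_slice(i, i * h, list(pts))
      }
      H <- (n - 1L) * h
      r_eff <- r + step / 4
      ref$area_lateral_smooth <- 2 * pi * r_eff * H
      ref$area_total_smooth <- 2 * pi * r_eff * H + 2 * pi * r_eff^2
      ref$volume_smooth <- pi * r_eff^2 * H
      ref$euler_characteristic <- 2L
    },
    knot_case = {
      n <- 2L
      if (is.null(sulcus_depth)) sulcus_depth <- 0.8 * r
      for (i in 0:1) {
        phi <- if (i == 0L) 0 else pi
        add_slice(i, i * h,
                  list(.sulcus_circle(r, np, phi, sulcus_depth,
                                      sulcus_width)))
      }
      ref$euler_characteristic <- 2L
    })
  stk <- contour_stack(label, slices, h)
  if (jitter_sd > 0) {
    stk$slices <- .with_seed(seed, lapply(stk$slices, function(sp) {
      sp$contours <- lapply(sp$contours, function(ct) {
        ct$points <- ct$points + matrix(
          stats::rnorm(length(ct$points), 0, jitter_sd), ncol = 2L)
        ct
      })
      sp
    }))
  }
  structure(list(stack = stk, reference = ref), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom '%s': ", x$reference$kind))
  print(x$stack)
  invisible(x)
}

## contours of a torus (ring radius R in a plane containing the z axis,
## tube radius r) cut at height z0
.torus_slice <- function(z0, R, r, np) {
  lim <- (abs(z0) - R) / r
  if (lim <= -1) {
    # two loops: x > 0 and x < 0 branches
    al <- 2 * pi * (seq_len(np) - 1L) / np
    x <- sqrt(pmax((R + r * cos(al))^2 - z0^2, 0))
    y <- r * sin(al)
    list(cbind(x, y), cbind(-x, y))
  } else {
    amax <- acos(min(lim, 1))
    if (amax < 1e-6) stop("torus slice degenerate at z0 = ", z0)
    n2 <- max(3L, ceiling(np / 2))
    al <- seq(-amax, amax, length.out = n2)
    x <- sqrt(pmax((R + r * cos(al))^2 - z0^2, 0))
    y <- r * sin(al)
    pts <- rbind(cbind(x, y), cbind(-rev(x[-c(1L, n2)]), rev(y[-c(1L, n2)])))
    list(pts)
  }
}

## circle of radius r with a V-shaped sulcus of given depth at angle phi
.sulcus_circle <- function(r, np, phi, depth, width) {
  n_arc <- max(np - 3L, 8L)
  th <- phi + width + (2 * pi - 2 * width) * (seq_len(n_arc) - 1L) /
    (n_arc - 1L)
  arc <- cbind(r * cos(th), r * sin(th))
  rho <- r - depth
  notch <- rbind(c(rho * cos(phi - width / 2), rho * sin(phi - width / 2)),
                 c(rho * cos(phi + width / 2), rho * sin(phi + width / 2)))
  rbind(arc, notch)
}

#' Drop slices from a stack (resolution degradation)
#'
#' Keeps every `k`-th slice (the first slice always kept) and multiplies
#' the gap accordingly — emulating sparse manual segmentation where only
#' every other traced slice is used.
#'
#' @param stack a [contour_stack].
#' @param keep_every_k keep slices at positions 1, k+1, 2k+1, ...
#' @return a [contour_stack] with gap `k * h`.
#' @export
degrade_resolution <- function(stack, keep_every_k = 2L) {
  k <- as.integer(keep_every_k)
  if (k < 1L) stop("keep_every_k must be >= 1")
  if (k == 1L) return(stack)
  keep <- seq(1L, length(stack$slices), by = k)
  slices <- stack$slices[keep]
  for (i in seq_along(slices)) {
    slices[[i]]$index <- i - 1L
    slices[[i]]$contours <- lapply(slices[[i]]$contours, function(ct) {
      ct$slice_index <- i - 1L
      ct
    })
  }
  contour_stack(stack$structure, slices, stack$gap * k)
}
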
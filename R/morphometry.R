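# Slice-based analytical approximation (AA) of lateral area and volume,
# with nesting-parity corrections, and the derived cortical metrics
# (thickness, gyrification index, minimum-gap rule).

#' Effective area and perimeter of one slice
#'
#' Aggregates all (selected) contours of a slice plane into the effective
#' cross-sectional area S_n and perimeter P_n used by the analytical
#' approximation: perimeters always add, while absolute areas are summed
#' algebraically with sign (-1)^depth, where depth is the containment
#' nesting depth — an annulus contributes outer minus inner, an island
#' inside the hole adds back, and so on.
#'
#' @param plane a [slice_plane].
#' @param label optional character vector of contour labels to include;
#'   `NULL` uses every contour of the plane.
#' @return a list of class `"slice_aggregate"` with fields `S` (mm^2), `P`
#'   (mm), `slice_index`, `n_contours`.
#' @export
slice_aggregate <- function(plane, label = NULL) {
  stopifnot(inherits(plane, "slice_plane"))
  cts <- plane$contours
  if (!is.null(label))
    cts <- Filter(function(ct) ct$label %in% label, cts)
  if (!length(cts)) {
    return(structure(list(S = 0, P = 0, slice_index = plane$index,
                          n_contours = 0L), class = "slice_aggregate"))
  }
  depth <- vapply(cts, containment_depth, integer(1), others = cts)
  S <- sum(vapply(seq_along(cts), function(i)
    (-1)^depth[i] * abs(signed_area(cts[[i]])), numeric(1)))
  P <- sum(vapply(cts, perimeter_length, numeric(1)))
  structure(list(S = S, P = P, slice_index = plane$index,
                 n_contours = length(cts)),
            class = "slice_aggregate")
}

## Coerce a stack + label into the (S, P) series
.aggregate_series <- function(stack, label = NULL) {
  aggs <- lapply(stack$slices, slice_aggregate, label = label)
  list(S = vapply(aggs, `[[`, numeric(1), "S"),
       P = vapply(aggs, `[[`, numeric(1), "P"))
}

.aa_series <- function(aggregates) {
  if (inherits(aggregates, "slice_aggregate")) aggregates <- list(aggregates)
  if (is.list(aggregates) && length(aggregates) &&
      inherits(aggregates[[1]], "slice_aggregate")) {
    list(S = vapply(aggregates, `[[`, numeric(1), "S"),
         P = vapply(aggregates, `[[`, numeric(1), "P"))
  } else if (is.list(aggregates) && all(c("S", "P") %in% names(aggregates))) {
    aggregates
  } else stop("aggregates must be slice_aggregate objects or a list(S, P)")
}

#' Analytical lateral surface area of a slice stack
#'
#' Per-gap frustum-style rule: each pair of consecutive slices contributes
#' sqrt((S2 - S1)^2 + (h (P1 + P2) / 2)^2), the slant area of a conical
#' band whose cross-section changes from S1 to S2 over the gap h. For
#' constant areas the rule degenerates to h * P per gap.
#'
#' @param aggregates a list of [slice_aggregate]s in slice order, or a
#'   `list(S=, P=)` of numeric vectors.
#' @param h slice gap in mm (uniform; the approximation assumes it).
#' @return lateral area in mm^2.
#' @export
aa_lateral_area <- function(aggregates, h) {
  ser <- .aa_series(aggregates)
  S <- ser$S; P <- ser$P
  n <- length(S)
  if (n < 2L) stop("at least 2 slice aggregates are required")
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a single positive gap in mm; nonuniform gaps are not supported")
  i <- seq_len(n - 1L)
  sum(sqrt((S[i + 1L] - S[i])^2 + (h * (P[i] + P[i + 1L]) / 2)^2))
}

#' Analytical volume of a slice stack
#'
#' Conical-frustum rule per gap: h (S1 + S2 + sqrt(S1 S2)) / 3, exact for
#' linear-radius (conical) transitions between similar cross-sections.
#'
#' @inheritParams aa_lateral_area
#' @return volume in mm^3.
#' @export
aa_volume <- function(aggregates, h) {
  ser <- .aa_series(aggregates)
  S <- ser$S
  n <- length(S)
  if (n < 2L) stop("at least 2 slice aggregates are required")
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a single positive gap in mm")
  if (any(S < 0))
    stop("negative effective slice area; check contour nesting/labels")
  i <- seq_len(n - 1L)
  sum(h * (S[i] + S[i + 1L] + sqrt(S[i] * S[i + 1L])) / 3)
}

#' Mean cortical thickness
#'
#' T = (V_t - V_wm) / A_t: the gray-matter sheet volume (total minus
#' white-matter volume) spread over the total pial area.
#'
#' @param v_t total (pial) volume in mm^3.
#' @param v_wm white-matter volume in mm^3.
#' @param a_t total pial surface area in mm^2, > 0.
#' @return thickness in mm.
#' @export
cortical_thickness <- function(v_t, v_wm, a_t) {
  if (!is.finite(a_t) || a_t <= 0) stop("a_t must be positive")
  (v_t - v_wm) / a_t
}

#' Gyrification index
#'
#' GI = A_t / A_e: total pial area over exposed (envelope) area; 1 for a
#' perfectly smooth (lissencephalic) cortex.
#'
#' @param a_t total pial area, mm^2.
#' @param a_e exposed area, mm^2, > 0.
#' @return dimensionless ratio.
#' @export
gyrification_index <- function(a_t, a_e) {
  if (!is.finite(a_e) || a_e <= 0) stop("a_e must be positive")
  a_t / a_e
}

#' Minimum slice gap for faithful reconstruction
#'
#' A sulcus of a cortex with thickness T spans about 2T (two gray-matter
#' walls); sampling it at the Nyquist rate requires a slice gap of at most
#' T, so the minimum-gap estimate is simply the thickness.
#'
#' @param t_mm cortical thickness in mm, > 0.
#' @return the gap threshold in mm.
#' @export
min_gap_estimate <- function(t_mm) {
  if (!is.finite(t_mm) || t_mm <= 0) stop("thickness must be positive")
  t_mm
}

#' Check a stack's slice gap against the minimum-gap rule
#'
#' @param h slice gap in mm (or a [contour_stack]).
#' @param t_mm cortical thickness in mm.
#' @return list with `gap`, `gap_min`, `satisfied` (h <= gap_min) and a
#'   `resolution` label (`"full"` or `"low"`).
#' @export
gap_resolution_check <- function(h, t_mm) {
  if (inherits(h, "contour_stack")) h <- h$gap
  gmin <- min_gap_estimate(t_mm)
  ok <- h <= gmin
  list(gap = h, gap_min = gmin, satisfied = ok,
       resolution = if (ok) "full" else "low")
}

#' Analytical-approximation morphometry report for a contour stack
#'
#' Runs the slice aggregation and the analytical area/volume rules for the
#' gray-matter, white-matter and exposed-surface labels of a stack, and
#' derives thickness, gyrification index and the minimum-gap check.
#'
#' @param stack a [contour_stack] containing contours labelled with the
#'   `gm`, `wm`, `exposed` label names.
#' @param gm,wm,exposed label names used in the stack.
#' @return a data.frame with one row per quantity (`V_t`, `V_wm`, `A_t`,
#'   `A_e`, `T`, `GI`, `gap`, `gap_min`) and column `AA`.
#' @export
aa_morphometry <- function(stack, gm = "GM", wm = "WM", exposed = "exposed") {
  h <- stack$gap
  ser_gm <- .aggregate_series(stack, gm)
  v_t <- aa_volume(ser_gm, h)
  a_t <- aa_lateral_area(ser_gm, h)
  has_wm <- any(vapply(stack$slices, function(sp)
    any(vapply(sp$contours, function(ct) ct$label %in% wm, logical(1))),
    logical(1)))
  v_wm <- if (has_wm) aa_volume(.aggregate_series(stack, wm), h) else NA_real_
  has_exp <- any(vapply(stack$slices, function(sp)
    any(vapply(sp$contours, function(ct) ct$label %in% exposed, logical(1))),
    logical(1)))
  a_e <- if (has_exp) aa_lateral_area(.aggregate_series(stack, exposed), h)
         else NA_real_
  t_mm <- if (is.finite(v_wm)) cortical_thickness(v_t, v_wm, a_t) else NA_real_
  gi <- if (is.finite(a_e)) gyrification_index(a_t, a_e) else NA_real_
  gmin <- if (is.finite(t_mm) && t_mm > 0) min_gap_estimate(t_mm) else NA_real_
  data.frame(quantity = c("V_t", "V_wm", "A_t", "A_e", "T", "GI",
                          "gap", "gap_min"),
             AA = c(v_t, v_wm, a_t, a_e, t_mm, gi, h, gmin),
             row.names = NULL)
}
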
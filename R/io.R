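# Readers and writers: the cstack-1 contour-stack JSON dialect, OBJ / PLY
# (ascii) / STL (binary) meshes, and CSV/JSON morphometry reports.

#' Read a contour stack from cstack-1 JSON
#'
#' The canonical serialization of a traced stack (the dialect a
#' segmentation session would export): top level
#' `{version, structure, gap_mm, slices:[{index, z_mm,
#' contours:[{label, points:[[x,y],...]}]}]}` with points in mm and
#' implicit ring closure. The file is validated structurally (see
#' `inst/extdata/cstack-1-schema.json`) and every contour is normalised on
#' load: consecutive duplicates removed, self-crossings repaired, and
#' orientation forced clockwise.
#'
#' @param path path to a cstack-1 JSON file.
#' @param normalize repair crossings and force clockwise orientation
#'   (default TRUE).
#' @param quiet suppress per-contour normalisation messages.
#' @return a [contour_stack].
#' @export
read_stack <- function(path, normalize = TRUE, quiet = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  .validate_cstack(x, path)
  slices <- lapply(x$slices, function(sl) {
    cts <- lapply(sl$contours, function(ct) {
      pts <- do.call(rbind, lapply(ct$points, unlist))
      if (is.null(pts) || ncol(pts) != 2L)
        stop(sprintf("%s: slice %d: points must be [[x,y],...]",
                     path, sl$index))
      co <- contour(pts, z = sl$z_mm, label = ct$label,
                    slice_index = sl$index)
      if (normalize) {
        n0 <- nrow(co$points)
        co2 <- ensure_clockwise(repair_self_crossings(co))
        if (!quiet && nrow(co2$points) != n0)
          message(sprintf("slice %d '%s': repaired self-crossings (%d -> %d points)",
                          sl$index, ct$label, n0, nrow(co2$points)))
        co2
      } else co
    })
    slice_plane(sl$index, sl$z_mm, cts)
  })
  contour_stack(x$structure, slices, x$gap_mm)
}

.validate_cstack <- function(x, path = "<json>") {
  need <- c("structure", "gap_mm", "slices")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("%s: not a cstack-1 file; missing field(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (!is.null(x$version) && !identical(x$version, "cstack-1"))
    stop(sprintf("%s: unsupported version '%s'", path, x$version))
  if (!is.numeric(x$gap_mm) || length(x$gap_mm) != 1L || x$gap_mm <= 0)
    stop(sprintf("%s: gap_mm must be a positive number", path))
  if (!length(x$slices)) stop(sprintf("%s: empty slices", path))
  for (sl in x$slices) {
    if (is.null(sl$index) || is.null(sl$z_mm) || is.null(sl$contours))
      stop(sprintf("%s: each slice needs index, z_mm, contours", path))
    for (ct in sl$contours) {
      if (is.null(ct$points) || length(ct$points) < 3L)
        stop(sprintf("%s: slice %d: contour with fewer than 3 points",
                     path, sl$index))
      zlens <- lengths(ct$points)
      if (any(zlens != 2L))
        stop(sprintf("%s: slice %d: points must be [x,y] pairs (mixed z within a slice is not representable)",
                     path, sl$index))
    }
  }
  invisible(TRUE)
}

#' Write a contour stack as cstack-1 JSON
#'
#' Numbers are written at full precision, so a write/read cycle reproduces
#' the stack exactly.
#'
#' @param stack a [contour_stack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  x <- list(
    version = "cstack-1",
    structure = stack$structure,
    gap_mm = stack$gap,
    slices = lapply(stack$slices, function(sl) {
      list(index = sl$index, z_mm = sl$z,
           contours = lapply(sl$contours, function(ct) {
             list(label = ct$label,
                  points = lapply(seq_len(nrow(ct$points)),
                                  function(i) ct$points[i, ]))
           }))
    }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write a triangle mesh to OBJ, PLY (ascii) or STL (binary)
#'
#' @param mesh a [trimesh].
#' @param path output path; the format is inferred from the extension when
#'   `format` is missing.
#' @param format `"obj"`, `"ply"` or `"stl"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply", "stl"))
  v <- mesh$vertices; f <- mesh$faces
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y",
                 "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      t1 <- v[f[i, ], , drop = FALSE]
      n <- .tri_normal(t1)
      l <- sqrt(sum(n^2)); if (l > 0) n <- n / l
      writeBin(as.numeric(c(n, t(t1))), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a triangle mesh written by [write_mesh]
#'
#' @param path path to an OBJ, ascii PLY or binary STL file.
#' @param format inferred from the extension when missing.
#' @return a [trimesh]. STL files, having no shared-vertex structure,
#'   are re-indexed by exact coordinate match.
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply", "stl"))
  if (format == "obj") {
    ln <- readLines(path)
    vl <- ln[startsWith(ln, "v ")]
    fl <- ln[startsWith(ln, "f ")]
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
      as.numeric(p[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
    trimesh(v, f)
  } else if (format == "ply") {
    ln <- readLines(path)
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", ln, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", ln, value = TRUE)))
    hdr <- which(ln == "end_header")
    v <- do.call(rbind, lapply(strsplit(ln[hdr + seq_len(nv)], "\\s+"),
                               function(p) as.numeric(p[1:3])))
    f <- do.call(rbind, lapply(strsplit(ln[hdr + nv + seq_len(nf)], "\\s+"),
                               function(p) as.integer(p[2:4]) + 1L))
    trimesh(v, f)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    verts <- matrix(0, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 2L, endian = "little")
      verts[3L * i - 2:0, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    }
    key <- paste(verts[, 1], verts[, 2], verts[, 3])
    uk <- !duplicated(key)
    ids <- match(key, key[uk])
    v <- verts[uk, , drop = FALSE]
    f <- matrix(ids, ncol = 3L, byrow = TRUE)
    trimesh(v, f)
  }
}

#' Write a morphometry report
#'
#' Rows are the standard summary quantities (`V_t`, `V_wm`, `A_t`, `A_e`,
#' `T`, `GI`, ...), columns one per method (`raw`, `smooth`, `AA`). Values
#' are reported at 2 decimals in mm-based units.
#'
#' @param report a data.frame with a `quantity` column and one numeric
#'   column per method.
#' @param path output path.
#' @param format `"json"` or `"csv"`; inferred from the extension when
#'   missing.
#' @param digits reporting precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL, digits = 2L) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("json", "csv"))
  num <- vapply(report, is.numeric, logical(1))
  report[num] <- lapply(report[num], round, digits = digits)
  if (format == "csv") {
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Write a mesh audit as JSON
#'
#' @param audit a `"mesh_audit"` from [mesh_audit].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  jsonlite::write_json(unclass(audit), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
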
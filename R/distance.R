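#' Signed surface-to-surface distance field
#'
#' For every vertex `p` of the compared (later) scan, finds the nearest
#' point `q` on the reference (earlier) surface through a spatial index and
#' records the displacement `p - q` and its signed length: positive when
#' `p` lies outside the reference (swelling excess), negative inside
#' (deficit). The sign comes from the reference surface's outward
#' pseudonormal at `q`; the reference's global orientation is normalized
#' from its signed volume first so "outward" is well defined.
#'
#' @param compared `triangle_mesh` hosting the field (the later scan).
#' @param reference `triangle_mesh` measured against (the earlier scan).
#' @param pair_label label such as `"T0-T1"`.
#' @return a `distance_field` list: `mesh` (compared, with the
#'   `signed_distance_mm` scalar and `displacement_mm` vectors attached),
#'   `signed_distance`, `displacement`, `pair_label`.
#' @export
signed_distance_field <- function(compared, reference, pair_label = "") {
  if (nrow(reference$vertices) == 0 || nrow(reference$faces) == 0)
    stop("signed_distance_field: empty reference mesh")
  mesh_validate(compared)
  ref <- reference
  # normalize global orientation so face normals point outward
  s <- signed_volume_sum(ref)
  if (s < 0) ref$faces <- ref$faces[, c(1, 3, 2), drop = FALSE]
  cp <- .cpp_closest_points(ref$vertices, ref$faces, compared$vertices)
  disp <- compared$vertices - cp$point
  sdist <- cp$sign * cp$distance
  out <- compared
  out$vertex_scalars[["signed_distance_mm"]] <- sdist
  out$vertex_vectors[["displacement_mm"]] <- disp
  structure(list(mesh = out, signed_distance = sdist, displacement = disp,
                 pair_label = pair_label), class = "distance_field")
}

#' Mean signed linear difference over a region of interest (mm)
#'
#' The unweighted arithmetic mean of the signed distances over the
#' base-mesh vertices lying inside the ROI — the single millimetric summary
#' of a scan pair. An area-weighted mean (each vertex weighted by one third
#' of its incident triangle area) is available as an option.
#'
#' @param field a `distance_field`.
#' @param roi a `roi_spec`, or NULL to average over all vertices.
#' @param area_weighted use area weights instead of vertex-uniform weights.
#' @return the mean in mm, with attributes `sd` and `n` (vertex count).
#' @export
mean_linear_difference <- function(field, roi = NULL, area_weighted = FALSE) {
  sdist <- field$signed_distance
  inside <- if (is.null(roi)) rep(TRUE, length(sdist)) else
    points_in_roi(field$mesh$vertices, roi)
  if (!any(inside))
    stop("empty ROI: no base-mesh vertices satisfy the region of interest")
  if (!area_weighted) {
    m <- mean(sdist[inside])
  } else {
    v <- field$mesh$vertices; f <- field$mesh$faces
    a <- v[f[, 1], , drop = FALSE]
    e1 <- v[f[, 2], , drop = FALSE] - a
    e2 <- v[f[, 3], , drop = FALSE] - a
    fa <- sqrt((e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
               (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
               (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2) / 2
    w <- numeric(nrow(v))
    acc <- rowsum(rep(fa / 3, 3), group = c(f[, 1], f[, 2], f[, 3]))
    w[as.integer(rownames(acc))] <- acc
    m <- sum(sdist[inside] * w[inside]) / sum(w[inside])
  }
  attr(m, "sd") <- if (sum(inside) > 1) sd(sdist[inside]) else 0
  attr(m, "n") <- sum(inside)
  m
}

#' Symmetric diverging colour for signed distances
#'
#' Maps `-span` to pure blue, 0 to white and `+span` to pure red, linearly,
#' clamping outside the span.
#'
#' @param values signed distances (mm).
#' @param span positive half-range (mm).
#' @return integer matrix n x 3 of 8-bit red, green, blue.
#' @export
diverging_color <- function(values, span) {
  if (span <= 0) stop("colormap span must be > 0")
  t <- pmax(-1, pmin(1, values / span))
  r <- ifelse(t >= 0, 255, round(255 * (1 + t)))
  g <- round(255 * (1 - abs(t)))
  b <- ifelse(t <= 0, 255, round(255 * (1 - t)))
  cbind(red = as.integer(r), green = as.integer(g), blue = as.integer(b))
}

#' Export a colour-mapped distance field
#'
#' Writes the base mesh with the `signed_distance_mm` vertex scalar plus an
#' 8-bit per-vertex colour from the symmetric blue-white-red diverging map,
#' to PLY or VTK polydata (STL cannot carry attributes and is refused).
#'
#' @param field a `distance_field`.
#' @param path output path (`.ply` or `.vtk`).
#' @param span positive half-range of the map in mm; default the 95th
#'   percentile of the absolute signed distance.
#' @param format `"auto"`, `"ply"` or `"vtk"`.
#' @return the path, invisibly.
#' @export
colormap_export <- function(field, path, span = NULL,
                            format = c("auto", "ply", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    if (ext == "stl")
      stop("STL cannot carry colour or scalar attributes; use PLY or VTK")
    format <- switch(ext, ply = "ply", vtk = "vtk",
                     stop("colormap export supports PLY or VTK, not '.", ext, "'"))
  }
  if (is.null(span)) {
    span <- as.numeric(stats::quantile(abs(field$signed_distance), 0.95))
    if (span <= 0) span <- 1
  }
  if (span <= 0) stop("colormap span must be > 0")
  cols <- diverging_color(field$signed_distance, span)
  mesh <- field$mesh
  if (format == "ply") {
    mesh$vertex_scalars$red <- cols[, 1]
    mesh$vertex_scalars$green <- cols[, 2]
    mesh$vertex_scalars$blue <- cols[, 3]
    write_ply(mesh, path)
  } else {
    write_vtk_polydata(mesh, path, extra_colors01 = cols / 255)
  }
  invisible(path)
}

#' Export displacement vectors for glyph rendering
#'
#' Writes every `stride`-th vertex position of the field's base mesh as a
#' VTK polydata point set with the displacement as a point vector
#' attribute, ready for arrow/glyph rendering.
#'
#' @param field a `distance_field`.
#' @param path output path (`.vtk`).
#' @param stride keep every `stride`-th vertex (default 1 = all).
#' @return the path, invisibly.
#' @export
displacement_vector_export <- function(field, path, stride = 1L) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  keep <- seq(1L, nrow(field$mesh$vertices), by = stride)
  v <- field$mesh$vertices[keep, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "swellkit displacement vectors",
               "ASCII", "DATASET POLYDATA"), con)
  writeLines(paste("POINTS", nrow(v), "double"), con)
  writeLines(paste(fmt_g(v[, 1]), fmt_g(v[, 2]), fmt_g(v[, 3])), con)
  writeLines(paste("VERTICES", nrow(v), 2 * nrow(v)), con)
  writeLines(paste(1L, seq_len(nrow(v)) - 1L), con)
  writeLines(paste("POINT_DATA", nrow(v)), con)
  writeLines("VECTORS displacement_mm double", con)
  d <- field$displacement[keep, , drop = FALSE]
  writeLines(paste(fmt_g(d[, 1]), fmt_g(d[, 2]), fmt_g(d[, 3])), con)
  invisible(path)
}
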
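#' Region-of-interest specification
#'
#' A convex region given as an intersection of half-spaces, each a plane
#' point plus inward unit normal. Points `p` with
#' `dot(p - point, normal) >= 0` for every half-space are inside.
#'
#' @param half_spaces list of `list(point = c(x, y, z), normal = c(x, y, z))`;
#'   normals are normalised to unit length.
#' @param label free-text label.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(half_spaces, label = "") {
  if (length(half_spaces) < 1) stop("RoiSpec needs at least one half-space")
  hs <- lapply(half_spaces, function(h) {
    n <- as.numeric(h$normal)
    len <- sqrt(sum(n^2))
    if (len == 0) stop("zero-length half-space normal")
    list(point = as.numeric(h$point), normal = n / len)
  })
  structure(list(half_spaces = hs, label = label), class = "roi_spec")
}

#' Region of interest from anatomical landmarks
#'
#' Builds the operated-hemiface region bounded, in the canonical frame, by
#' four axis-aligned planes through the ROI landmarks: the zygomatic arch
#' superiorly, the submandibular fossa inferiorly, the preauricular region
#' posteriorly and the facial midline medially. With `side = "right"` the
#' region lies at `x <=` midline, with `side = "left"` at `x >=` midline.
#'
#' @param landmarks a `landmark_set` in the canonical frame containing the
#'   four ROI landmarks and a `side`.
#' @return a `roi_spec` with four half-spaces.
#' @export
roi_from_landmarks <- function(landmarks) {
  miss <- setdiff(required_roi_landmarks, names(landmarks))
  if (length(miss))
    stop("missing ROI landmarks: ", paste(miss, collapse = ", "))
  zs <- landmarks$zygomatic_superior[3]
  zi <- landmarks$submandibular_inferior[3]
  yp <- landmarks$preauricular_posterior[2]
  xm <- landmarks$midline_anterior[1]
  if (zs <= zi)
    stop("inconsistent ROI: zygomatic (superior) plane at z=", zs,
         " is not above submandibular (inferior) plane at z=", zi)
  side <- attr(landmarks, "side")
  xsign <- if (identical(side, "left")) 1 else -1
  roi_spec(list(
    list(point = c(0, 0, zs), normal = c(0, 0, -1)),   # below zygomatic arch
    list(point = c(0, 0, zi), normal = c(0, 0, 1)),    # above submandibular
    list(point = c(0, yp, 0), normal = c(0, 1, 0)),    # anterior to preauricular
    list(point = c(xm, 0, 0), normal = c(xsign, 0, 0)) # operated side of midline
  ), label = paste0(side, " hemiface"))
}

#' Which points fall inside a region of interest
#'
#' @param points n x 3 matrix (mm).
#' @param roi a `roi_spec`.
#' @param tol slack (mm) applied to each plane, so points numerically on a
#'   boundary count as inside.
#' @return logical vector of length n.
#' @export
points_in_roi <- function(points, roi, tol = 1e-9) {
  points <- matrix(as.numeric(points), ncol = 3)
  inside <- rep(TRUE, nrow(points))
  for (h in roi$half_spaces) {
    d <- (points[, 1] - h$point[1]) * h$normal[1] +
         (points[, 2] - h$point[2]) * h$normal[2] +
         (points[, 3] - h$point[3]) * h$normal[3]
    inside <- inside & (d >= -tol)
  }
  inside
}

#' Clip a mesh by a single plane
#'
#' Keeps the geometry on the side the normal points to. Triangles crossing
#' the plane are split exactly at the plane: new vertices are placed on the
#' plane and per-vertex attributes are interpolated linearly. The output is
#' generally open along the cut.
#'
#' @param mesh a `triangle_mesh`.
#' @param point a point on the plane (mm).
#' @param normal plane normal; the kept side.
#' @param tol vertices within `tol` of the plane count as kept.
#' @return the clipped `triangle_mesh` (possibly empty).
#' @export
clip_by_plane <- function(mesh, point, normal, tol = 1e-9) {
  normal <- as.numeric(normal); normal <- normal / sqrt(sum(normal^2))
  v <- mesh$vertices
  d <- (v[, 1] - point[1]) * normal[1] + (v[, 2] - point[2]) * normal[2] +
       (v[, 3] - point[3]) * normal[3]
  keep_v <- d >= -tol
  f <- mesh$faces
  if (nrow(f) == 0) return(mesh)
  kin <- matrix(keep_v[f], ncol = 3)
  n_in <- rowSums(kin)
  full <- which(n_in == 3L)
  # any face not fully in/out has at least one vertex strictly past the
  # tol band (outside means d < -tol), so it genuinely crosses the plane
  crossing <- which(n_in == 1L | n_in == 2L)

  new_vert <- list()
  new_key <- character(0)
  edge_cut <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    # snap onto an endpoint when the plane passes (numerically) through it,
    # so cuts along existing vertices never spawn coincident duplicates
    if (t <= 1e-9) return(i)
    if (t >= 1 - 1e-9) return(j)
    key <- paste(min(i, j), max(i, j))
    hit <- match(key, new_key)
    if (!is.na(hit)) return(nrow(v) + hit)
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    new_vert[[length(new_vert) + 1]] <<- c(p, i, j, t)
    new_key[length(new_key) + 1] <<- key
    nrow(v) + length(new_vert)
  }
  tris <- vector("list", length(crossing))
  for (k in seq_along(crossing)) {
    fi <- f[crossing[k], ]
    inn <- keep_v[fi]
    # rotate so pattern starts at an inside vertex
    rot <- which(inn)[1] - 1
    if (rot > 0) { fi <- fi[c((rot + 1):3, 1:rot)]; inn <- keep_v[fi] }
    if (sum(inn) == 1L) {
      a <- fi[1]; b <- fi[2]; cc <- fi[3]
      ab <- edge_cut(a, b); ca <- edge_cut(cc, a)
      tris[[k]] <- matrix(c(a, ab, ca), 1, 3)
    } else {
      # two inside: ensure fi = (in, in, out) by rotating once more if needed
      if (!inn[2]) { fi <- fi[c(3, 1, 2)]; inn <- keep_v[fi] }
      a <- fi[1]; b <- fi[2]; cc <- fi[3]
      bc <- edge_cut(b, cc); ca <- edge_cut(cc, a)
      tris[[k]] <- matrix(c(a, b, bc, a, bc, ca), 2, 3, byrow = TRUE)
    }
  }
  nv_new <- length(new_vert)
  verts <- rbind(v, if (nv_new) t(vapply(new_vert, function(x) x[1:3],
                                         numeric(3))) else NULL)
  faces <- rbind(f[full, , drop = FALSE], do.call(rbind, tris))
  if (!is.null(faces) && nrow(faces) > 0) {
    # snapping can degenerate a split triangle to a repeated-index sliver
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    faces <- faces[!degen, , drop = FALSE]
  }
  scalars <- mesh$vertex_scalars
  vectors <- mesh$vertex_vectors
  if (nv_new) {
    ii <- vapply(new_vert, function(x) x[4], 0)
    jj <- vapply(new_vert, function(x) x[5], 0)
    tt <- vapply(new_vert, function(x) x[6], 0)
    scalars <- lapply(scalars, function(s)
      c(s, s[ii] + tt * (s[jj] - s[ii])))
    vectors <- lapply(vectors, function(m)
      rbind(m, m[ii, , drop = FALSE] +
              tt * (m[jj, , drop = FALSE] - m[ii, , drop = FALSE])))
  }
  if (is.null(faces) || nrow(faces) == 0) {
    out <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                         metadata = mesh$metadata)
    attr(out, "empty_clip") <- TRUE
    return(out)
  }
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  triangle_mesh(verts[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3),
                vertex_scalars = lapply(scalars, function(s) s[used]),
                vertex_vectors = lapply(vectors, function(m)
                  m[used, , drop = FALSE]),
                metadata = mesh$metadata)
}

#' Clip a mesh to a region of interest
#'
#' Applies every half-space of the ROI in turn with `clip_by_plane`.
#' Triangles fully inside are kept, fully outside dropped, and crossing
#' triangles are split exactly at each plane; the result is generally open
#' along the clip boundary. An empty result is returned (with a warning)
#' when nothing survives.
#'
#' @param mesh a `triangle_mesh`.
#' @param roi a `roi_spec`.
#' @return the clipped `triangle_mesh`.
#' @export
clip_to_roi <- function(mesh, roi) {
  out <- mesh
  for (h in roi$half_spaces) {
    out <- clip_by_plane(out, h$point, h$normal)
    if (nrow(out$faces) == 0) {
      warning("ROI clip produced an empty mesh")
      attr(out, "empty_clip") <- TRUE
      return(out)
    }
  }
  out
}

#' Serialize / deserialize a region of interest as JSON
#'
#' @param roi a `roi_spec`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return `roi_to_json`: path or JSON string; `roi_from_json`: a `roi_spec`.
#' @export
roi_to_json <- function(roi, path = NULL) {
  obj <- list(label = roi$label,
              half_spaces = lapply(roi$half_spaces, function(h)
                list(point = h$point, normal = h$normal)))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname roi_to_json
#' @param json JSON string or file path.
#' @export
roi_from_json <- function(json) {
  src <- if (file.exists(json)) paste(readLines(json, warn = FALSE), collapse = "") else json
  obj <- jsonlite::fromJSON(src, simplifyDataFrame = FALSE)
  roi_spec(obj$half_spaces, label = obj$label)
}
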
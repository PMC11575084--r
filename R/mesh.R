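#' Triangle surface mesh
#'
#' The universal currency of the pipeline: an indexed triangle surface in
#' millimetres with optional named per-vertex scalar and 3-vector attributes
#' and a free-form metadata block.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param vertex_scalars named list of numeric vectors, one value per vertex.
#' @param vertex_vectors named list of n x 3 numeric matrices.
#' @param metadata named list of free-form header values.
#' @param validate check the mesh invariants (default TRUE).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces,
                          vertex_scalars = list(),
                          vertex_vectors = list(),
                          metadata = list(),
                          validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  m <- structure(list(vertices = vertices, faces = faces,
                      vertex_scalars = vertex_scalars,
                      vertex_vectors = vertex_vectors,
                      metadata = metadata),
                 class = "triangle_mesh")
  if (validate) mesh_validate(m)
  m
}

#' Validate triangle-mesh invariants
#'
#' Checks finite coordinates, in-range face indices, three distinct indices
#' per face and one attribute entry per vertex. Errors on violation.
#'
#' @param mesh a `triangle_mesh`.
#' @return the mesh, invisibly.
#' @export
mesh_validate <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh has NaN/Inf vertex coordinates")
  n <- nrow(v)
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > n) stop("face index out of range [1, ", n, "]")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("face with repeated vertex indices (degenerate)")
  }
  for (nm in names(mesh$vertex_scalars)) {
    if (length(mesh$vertex_scalars[[nm]]) != n)
      stop("vertex scalar '", nm, "' has ", length(mesh$vertex_scalars[[nm]]),
           " entries for ", n, " vertices")
  }
  for (nm in names(mesh$vertex_vectors)) {
    vv <- mesh$vertex_vectors[[nm]]
    if (!is.matrix(vv) || nrow(vv) != n || ncol(vv) != 3)
      stop("vertex vector '", nm, "' is not an n x 3 matrix")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (length(x$vertex_scalars))
    cat("  scalars:", paste(names(x$vertex_scalars), collapse = ", "), "\n")
  if (length(x$vertex_vectors))
    cat("  vectors:", paste(names(x$vertex_vectors), collapse = ", "), "\n")
  if (length(x$metadata))
    cat("  metadata keys:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Strip identifying information from a mesh
#'
#' Empties the metadata block and removes colour/texture attributes while
#' leaving the geometry untouched, so a scan can circulate without any
#' identity linkage in its header.
#'
#' @param mesh a `triangle_mesh`.
#' @return the anonymized mesh; vertices and faces are identical to the input.
#' @export
anonymize_mesh <- function(mesh) {
  mesh_validate(mesh)
  keep <- !grepl("^(red|green|blue|alpha|color|colour|texture)",
                 names(mesh$vertex_scalars), ignore.case = TRUE)
  mesh$vertex_scalars <- mesh$vertex_scalars[keep]
  keepv <- !grepl("^(color|colour|texture|rgb)",
                  names(mesh$vertex_vectors), ignore.case = TRUE)
  mesh$vertex_vectors <- mesh$vertex_vectors[keepv]
  mesh$metadata <- list()
  mesh
}

# Undirected edge table: one row per undirected edge with its face count,
# plus the directed half-edge list. Used by diagnostics, closing, volume.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  he_face <- rep.int(seq_len(nrow(f)), 3L)
  a <- pmin(he_from, he_to)
  b <- pmax(he_from, he_to)
  key <- paste(a, b)
  grp <- match(key, unique(key))
  cnt <- tabulate(grp)
  list(he_from = he_from, he_to = he_to, he_face = he_face,
       edge_of_halfedge = grp, edge_count = cnt,
       edge_a = a[!duplicated(grp)], edge_b = b[!duplicated(grp)])
}

#' Mesh diagnostics
#'
#' Counts vertices, faces and boundary loops and reports watertightness and
#' orientation consistency. A mesh is watertight when it has no boundary
#' loops and every edge is shared by exactly two faces; it is consistently
#' oriented when every interior edge is traversed once in each direction.
#'
#' @param mesh a `triangle_mesh`.
#' @return a `mesh_diagnostics` list with fields `n_vertices`, `n_faces`,
#'   `n_boundary_loops`, `is_watertight`, `is_consistently_oriented`, `bbox`.
#' @export
diagnose_mesh <- function(mesh) {
  mesh_validate(mesh)
  e <- mesh_edges(mesh)
  boundary <- which(e$edge_count == 1L)
  n_loops <- 0L
  if (length(boundary) > 0) {
    # connected components of the undirected boundary-edge graph
    ea <- e$edge_a[boundary]; eb <- e$edge_b[boundary]
    verts <- sort(unique(c(ea, eb)))
    parent <- seq_along(verts)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    ia <- match(ea, verts); ib <- match(eb, verts)
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[rb] <- ra
    }
    n_loops <- length(unique(vapply(seq_along(verts), find, integer(1))))
  }
  all_shared_by_2 <- length(e$edge_count) == 0 || all(e$edge_count == 2L)
  # orientation: each undirected edge's directed traversals must all differ
  dir_key <- paste(e$he_from, e$he_to)
  consistently <- !anyDuplicated(dir_key) && all(e$edge_count <= 2L)
  bbox <- if (nrow(mesh$vertices)) apply(mesh$vertices, 2, range) else
    matrix(NA_real_, 2, 3)
  structure(list(
    n_vertices = nrow(mesh$vertices),
    n_faces = nrow(mesh$faces),
    n_boundary_loops = n_loops,
    is_watertight = n_loops == 0L && all_shared_by_2 && nrow(mesh$faces) > 0,
    is_consistently_oriented = consistently,
    bbox = bbox), class = "mesh_diagnostics")
}

#' @export
print.mesh_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("mesh_diagnostics: %d vertices, %d faces, ",
                     "%d boundary loop(s)\n  watertight: %s, ",
                     "consistently oriented: %s\n"),
              x$n_vertices, x$n_faces, x$n_boundary_loops,
              x$is_watertight, x$is_consistently_oriented))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#'
#' @param mesh a `triangle_mesh`.
#' @return sum of triangle areas in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) return(0)
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Apply a vertex permutation and face reordering to a mesh
#'
#' Relabels vertices by `vperm` (new index of each old vertex) and reorders
#' faces by `forder`; attributes follow the vertices. Geometry is unchanged.
#' Mainly used to test permutation invariance of downstream measures.
#'
#' @param mesh a `triangle_mesh`.
#' @param vperm integer permutation of `1:n_vertices`.
#' @param forder integer permutation of `1:n_faces`.
#' @return the reindexed mesh.
#' @export
reindex_mesh <- function(mesh, vperm = NULL, forder = NULL) {
  n <- nrow(mesh$vertices)
  if (is.null(vperm)) vperm <- seq_len(n)
  if (is.null(forder)) forder <- seq_len(nrow(mesh$faces))
  inv <- integer(n); inv[vperm] <- seq_len(n)
  v <- mesh$vertices[inv, , drop = FALSE]
  f <- matrix(vperm[mesh$faces], ncol = 3)[forder, , drop = FALSE]
  triangle_mesh(v, f,
                vertex_scalars = lapply(mesh$vertex_scalars, function(s) s[inv]),
                vertex_vectors = lapply(mesh$vertex_vectors,
                                        function(m) m[inv, , drop = FALSE]),
                metadata = mesh$metadata)
}

# vertex normals, area-weighted (cross-product magnitude weighting)
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  n <- matrix(0, nrow(v), 3)
  idx <- c(f[, 1], f[, 2], f[, 3])
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}
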
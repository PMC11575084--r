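#' Proper rigid motion
#'
#' A rotation plus translation, applied as `p -> R p + t`. The rotation must
#' be orthonormal with determinant +1.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @param validate check orthonormality (default TRUE).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            validate = TRUE) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (validate) {
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
      stop("rotation is not orthonormal (tolerance 1e-8)")
    if (abs(det(rotation) - 1) > 1e-8)
      stop("rotation determinant is ", det(rotation), ", not +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation,
                  validate = FALSE)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return the inverse motion.
#' @export
invert_transform <- function(t) {
  rt <- t(t$rotation)
  rigid_transform(rt, -as.vector(rt %*% t$translation), validate = FALSE)
}

#' Apply a rigid transform to a point matrix
#'
#' @param points n x 3 matrix (mm).
#' @param t a `rigid_transform`.
#' @return transformed n x 3 matrix.
#' @export
transform_points <- function(points, t) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points %*% t(t$rotation), 2, -t$translation)
}

#' Apply a rigid transform to a mesh
#'
#' Vertices are rotated then translated; faces and scalar attributes are
#' unchanged; vector attributes are rotated with the motion.
#'
#' @param mesh a `triangle_mesh`.
#' @param t a `rigid_transform`.
#' @return the transformed mesh.
#' @export
apply_transform <- function(mesh, t) {
  mesh$vertices <- transform_points(mesh$vertices, t)
  colnames(mesh$vertices) <- c("x", "y", "z")
  mesh$vertex_vectors <- lapply(mesh$vertex_vectors,
                                function(vv) vv %*% t(t$rotation))
  mesh
}

#' Draw a random rigid motion
#'
#' Rotation about a uniformly random axis by an angle uniform on
#' `[0, max_angle_deg]`, translation uniform in the cube
#' `[-max_translation, max_translation]^3` clamped to the stated magnitude.
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param max_angle_deg maximum rotation angle in degrees.
#' @param max_translation maximum translation magnitude per axis (mm).
#' @return a `rigid_transform`.
#' @export
random_rigid_transform <- function(max_angle_deg, max_translation) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_angle_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  tr <- runif(3, -max_translation, max_translation)
  rigid_transform(R, tr, validate = FALSE)
}

#' Least-squares rigid fit between paired point sets
#'
#' Closed-form Kabsch/Umeyama solution: the proper rigid motion minimising
#' the sum of squared distances `|| R p_i + t - q_i ||^2`, via SVD of the
#' cross-covariance with determinant correction (no reflections).
#'
#' @param source n x 3 matrix of points to move.
#' @param target n x 3 matrix of corresponding points.
#' @param weights optional non-negative weights, length n.
#' @return a `rigid_transform` carrying `source` onto `target`.
#' @export
fit_rigid <- function(source, target, weights = NULL) {
  source <- matrix(as.numeric(source), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  stopifnot(nrow(source) == nrow(target), nrow(source) >= 3)
  if (is.null(weights)) weights <- rep(1, nrow(source))
  w <- weights / sum(weights)
  cs <- colSums(source * w)
  ct <- colSums(target * w)
  P <- sweep(source, 2, cs)
  Q <- sweep(target, 2, ct)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs), validate = FALSE)
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' @param t a `rigid_transform`.
#' @param path optional file path; when NULL a JSON string is returned.
#' @return `transform_to_json`: path or JSON string; `transform_from_json`:
#'   a `rigid_transform`.
#' @export
transform_to_json <- function(t, path = NULL) {
  obj <- list(rotation = unclass(t$rotation), translation = t$translation)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname transform_to_json
#' @param json JSON string or file path.
#' @export
transform_from_json <- function(json) {
  src <- if (file.exists(json)) paste(readLines(json, warn = FALSE), collapse = "") else json
  obj <- jsonlite::fromJSON(src)
  rigid_transform(matrix(unlist(obj$rotation), 3, 3),
                  as.numeric(obj$translation))
}
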
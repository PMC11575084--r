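#' Named anatomical landmark set
#'
#' Holds the named 3D points (mm) that define the canonical anatomical frame
#' and the region-of-interest boundary planes:
#' \itemize{
#'   \item canonical frame: `porion_left`, `porion_right`, `orbitale_left`
#'     (the Frankfurt-plane triplet) and `nasion`, `subnasale` (midsagittal);
#'   \item ROI boundary: `zygomatic_superior`, `submandibular_inferior`,
#'     `preauricular_posterior`, `midline_anterior`;
#'   \item `side`: `"left"` or `"right"`, the operated hemiface.
#' }
#'
#' @param ... named landmarks, each a length-3 numeric (mm), plus `side`.
#' @param points alternatively, a named list of length-3 numerics.
#' @param side operated hemiface, `"left"` or `"right"`.
#' @return an object of class `landmark_set` (a named list of points with a
#'   `side` attribute).
#' @export
landmark_set <- function(..., points = NULL, side = c("right", "left")) {
  if (is.null(points)) points <- list(...)
  side <- match.arg(side)
  pts <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3 || !all(is.finite(p)))
      stop("each landmark must be a finite length-3 coordinate")
    p
  })
  structure(pts, side = side, class = "landmark_set")
}

required_frame_landmarks <- c("porion_left", "porion_right", "orbitale_left",
                              "nasion")
required_roi_landmarks <- c("zygomatic_superior", "submandibular_inferior",
                            "preauricular_posterior", "midline_anterior")

#' Read / write a landmark file
#'
#' The landmark file is JSON mapping landmark name to `[x, y, z]` in mm,
#' with an optional `"side"` entry naming the operated hemiface.
#'
#' @param path file path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = ""))
  side <- if (!is.null(obj$side)) obj$side else "right"
  obj$side <- NULL
  landmark_set(points = obj, side = side)
}

#' @rdname read_landmarks
#' @param landmarks a `landmark_set`.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- c(lapply(unclass(landmarks), as.numeric),
           list(side = attr(landmarks, "side")))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE), path)
  invisible(path)
}

#' Apply a rigid transform to every landmark
#'
#' @param landmarks a `landmark_set`.
#' @param t a `rigid_transform`.
#' @return the transformed `landmark_set`.
#' @export
transform_landmarks <- function(landmarks, t) {
  pts <- lapply(unclass(landmarks), function(p)
    as.vector(t$rotation %*% p) + t$translation)
  landmark_set(points = pts, side = attr(landmarks, "side"))
}

#' Standardized anatomical orientation from landmarks
#'
#' Computes the rigid motion carrying a scan into the canonical anatomical
#' frame: the Frankfurt plane (through both porions and the left orbitale)
#' maps to a horizontal plane of constant z, the midsagittal plane (through
#' the nasion, orthogonal to Frankfurt, containing the porion-midpoint to
#' nasion direction) maps to x = 0, and the origin lands on the porion
#' midpoint. Axes: x left-to-right, y posterior-to-anterior, z
#' inferior-to-superior; units mm.
#'
#' @param landmarks a `landmark_set` containing at least `porion_left`,
#'   `porion_right`, `orbitale_left` and `nasion`.
#' @return the orienting `rigid_transform`.
#' @export
orient_by_landmarks <- function(landmarks) {
  miss <- setdiff(required_frame_landmarks, names(landmarks))
  if (length(miss))
    stop("missing canonical-frame landmarks: ", paste(miss, collapse = ", "))
  pl <- landmarks$porion_left
  pr <- landmarks$porion_right
  ol <- landmarks$orbitale_left
  na <- landmarks$nasion
  m <- (pl + pr) / 2
  u <- pr - pl
  v <- ol - m
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  # triangle area of the Frankfurt triplet must exceed 1 mm^2
  if (sqrt(sum(n^2)) / 2 <= 1)
    stop("degenerate landmarks: Frankfurt triplet is (near-)collinear ",
         "(triangle area <= 1 mm^2)")
  z <- n / sqrt(sum(n^2))
  yr <- na - m
  yp <- yr - sum(yr * z) * z
  if (sqrt(sum(yp^2)) < 1e-9)
    stop("degenerate landmarks: nasion lies on the porion-midpoint normal")
  y <- yp / sqrt(sum(yp^2))
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  if (sum(x * u) < 0) {
    z <- -z
    yp <- yr - sum(yr * z) * z
    y <- yp / sqrt(sum(yp^2))
    x <- c(y[2] * z[3] - y[3] * z[2],
           y[3] * z[1] - y[1] * z[3],
           y[1] * z[2] - y[2] * z[1])
  }
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  rigid_transform(R, -as.vector(R %*% m))
}
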
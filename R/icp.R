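# run code with a local, restored RNG state so seeded internals never
# disturb the caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for trimmed iterative-closest-point registration
#'
#' @param max_iterations iteration cap (default 100).
#' @param rms_change_tolerance stop when the trimmed RMS improves by less
#'   than this (mm, default 1e-4).
#' @param trim_fraction fraction of the worst correspondences discarded each
#'   iteration, in `[0, 0.5)` (default 0.10) — this is what lets a swollen
#'   cheek ride along without biasing the fit.
#' @param subsample_size number of source vertices used (default 5000).
#' @param seed integer seed driving the subsample draw (default 0).
#' @return a list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, rms_change_tolerance = 1e-4,
                       trim_fraction = 0.10, subsample_size = 5000L,
                       seed = 0L) {
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  if (rms_change_tolerance <= 0) stop("rms_change_tolerance must be > 0")
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_change_tolerance = rms_change_tolerance,
                 trim_fraction = trim_fraction,
                 subsample_size = as.integer(subsample_size),
                 seed = as.integer(seed)), class = "icp_params")
}

# one Gauss-Newton point-to-plane step: minimise sum of squared distances
# to the target's tangent planes at the current foot points, linearised
# about the current pose (rotation via Rodrigues on the solved axis-angle)
point_to_plane_step <- function(pts_moved, foot, normals) {
  r <- rowSums((pts_moved - foot) * normals)
  cxn <- cbind(pts_moved[, 2] * normals[, 3] - pts_moved[, 3] * normals[, 2],
               pts_moved[, 3] * normals[, 1] - pts_moved[, 1] * normals[, 3],
               pts_moved[, 1] * normals[, 2] - pts_moved[, 2] * normals[, 1])
  A <- cbind(cxn, normals)
  x <- tryCatch(solve(crossprod(A), -crossprod(A, r)),
                error = function(e) NULL)
  if (is.null(x)) return(identity_transform())
  w <- x[1:3]
  ang <- sqrt(sum(w^2))
  R <- if (ang < 1e-12) diag(3) else {
    ax <- w / ang
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  rigid_transform(R, x[4:6], validate = FALSE)
}

#' Rigid surface registration by trimmed point-to-surface ICP
#'
#' Aligns `source` onto `target` by iterating: (a) a seeded uniform
#' subsample of source vertices, (b) nearest-point-on-target-surface
#' correspondences through a spatial index, (c) rejection of the worst
#' `trim_fraction` of correspondences by distance, (d) a rigid pose update.
#' The update is the closed-form least-squares point-to-point fit (SVD of
#' the cross-covariance, determinant corrected) while the pose is far from
#' the surface, switching to Gauss-Newton point-to-plane steps (distance to
#' the target's tangent planes at the foot points) once the point-to-point
#' stage stalls — the tangent-plane objective removes the slow tangential
#' sliding mode and converges quadratically near the optimum. Stops at
#' `max_iterations` or when the trimmed RMS improves by less than
#' `rms_change_tolerance` in the plane stage. Deterministic given the seed.
#'
#' @param source `triangle_mesh` to move.
#' @param target `triangle_mesh` to align onto.
#' @param params an `icp_params`.
#' @param init initial `rigid_transform` (default identity).
#' @return a list: `transform` (source to target), `rms` (trimmed RMS, mm),
#'   `iterations`, `converged`, `rms_history`.
#' @export
icp_register <- function(source, target, params = icp_params(),
                         init = identity_transform()) {
  if (nrow(source$vertices) == 0 || nrow(target$vertices) == 0)
    stop("icp_register: empty source or target mesh")
  n <- nrow(source$vertices)
  idx <- with_local_seed(params$seed, {
    if (n <= params$subsample_size) seq_len(n)
    else sample.int(n, params$subsample_size)
  })
  pts <- source$vertices[idx, , drop = FALSE]
  n_keep <- max(3L, ceiling(length(idx) * (1 - params$trim_fraction)))
  trans <- init
  rms_prev <- Inf
  rms_hist <- numeric(0)
  converged <- FALSE
  iters <- 0L
  best <- list(rms = Inf, transform = init)
  plane_stage <- FALSE
  for (it in seq_len(params$max_iterations)) {
    iters <- it
    moved <- transform_points(pts, trans)
    cp <- .cpp_closest_points(target$vertices, target$faces, moved)
    ord <- order(cp$distance)[seq_len(n_keep)]
    rms <- sqrt(mean(cp$distance[ord]^2))
    rms_hist <- c(rms_hist, rms)
    if (rms < best$rms) best <- list(rms = rms, transform = trans)
    improvement <- rms_prev - rms
    if (is.finite(rms_prev) && improvement < params$rms_change_tolerance) {
      if (plane_stage) {
        converged <- TRUE
        break
      }
      plane_stage <- TRUE  # point-to-point stalled: switch objective
    } else if (is.finite(rms_prev) && improvement < 0.05 * rms_prev) {
      plane_stage <- TRUE  # slow tail: tangent planes converge faster
    }
    rms_prev <- rms
    if (plane_stage) {
      upd <- point_to_plane_step(moved[ord, , drop = FALSE],
                                 cp$point[ord, , drop = FALSE],
                                 cp$normal[ord, , drop = FALSE])
      trans <- compose_transforms(upd, trans)
    } else {
      # absolute fit from the original subsample to current correspondences
      trans <- fit_rigid(pts[ord, , drop = FALSE],
                         cp$point[ord, , drop = FALSE])
    }
  }
  # one more correspondence pass so the returned RMS matches the returned
  # transform even when the loop exits at max_iterations
  moved <- transform_points(pts, trans)
  cp <- .cpp_closest_points(target$vertices, target$faces, moved)
  ord <- order(cp$distance)[seq_len(n_keep)]
  rms <- sqrt(mean(cp$distance[ord]^2))
  if (rms < best$rms) best <- list(rms = rms, transform = trans)
  if (!converged)
    warning("icp_register did not converge within ", params$max_iterations,
            " iterations (final trimmed RMS ", signif(best$rms, 4), " mm)")
  list(transform = best$transform, rms = best$rms, iterations = iters,
       converged = converged, rms_history = rms_hist)
}
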
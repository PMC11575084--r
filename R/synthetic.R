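# base icosahedron, unit circumradius
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

subdivide_once <- function(v, f) {
  nv <- nrow(v)
  key <- character(0)
  mid_of <- integer(0)
  newv <- list()
  midpoint <- function(i, j) {
    k <- paste(min(i, j), max(i, j))
    hit <- match(k, key)
    if (!is.na(hit)) return(mid_of[hit])
    p <- (v[i, ] + v[j, ]) / 2
    newv[[length(newv) + 1]] <<- p
    key[length(key) + 1] <<- k
    id <- nv + length(newv)
    mid_of[length(mid_of) + 1] <<- id
    id
  }
  out <- matrix(0L, 4 * nrow(f), 3)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    out[(4 * t - 3):(4 * t), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                        c(cc, ca, bc), c(ab, bc, ca))
  }
  list(v = rbind(v, do.call(rbind, newv)), f = out)
}

#' Icosphere: subdivided icosahedron projected to a sphere
#'
#' Subdivision level `n` yields `10 * 4^n + 2` vertices and `20 * 4^n`
#' faces; the mesh is watertight and consistently outward-oriented.
#'
#' @param subdivision non-negative integer refinement level.
#' @param radius sphere radius (mm, default 1).
#' @param center sphere centre (default origin).
#' @return a `triangle_mesh`.
#' @export
icosphere <- function(subdivision = 3, radius = 1, center = c(0, 0, 0)) {
  ico <- icosahedron()
  v <- ico$v; f <- ico$f
  for (k in seq_len(subdivision)) {
    s <- subdivide_once(v, f)
    v <- s$v / sqrt(rowSums(s$v^2))
    f <- s$f
  }
  v <- v / sqrt(rowSums(v^2))
  triangle_mesh(sweep(v * radius, 2, -as.numeric(center)), f)
}

#' Flat rectangular grid patch in the z = 0 plane
#'
#' A `nx` x `ny` vertex grid triangulated into `2 (nx-1)(ny-1)` upward-facing
#' triangles, centred on the origin. Open along its rim; used as the
#' analytic fixture for bump-volume checks.
#'
#' @param width,height extents in mm.
#' @param nx,ny vertex counts per side.
#' @return a `triangle_mesh`.
#' @export
grid_patch <- function(width = 100, height = 100, nx = 101, ny = 101) {
  xs <- seq(-width / 2, width / 2, length.out = nx)
  ys <- seq(-height / 2, height / 2, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  # counter-clockwise when viewed from +z, so normals point up
  f <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
             cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  triangle_mesh(v, f)
}

#' Synthetic head surface with anatomical landmarks
#'
#' A watertight ellipsoid (subdivided icosahedron scaled by the semi-axes)
#' standing in for a face scan, with a deterministic landmark set laid out
#' in the canonical frame: porions on the lateral axis (their midpoint at
#' the origin, so `orient_by_landmarks` returns the identity), orbitale and
#' nasion on the anterior side, and ROI landmarks framing the operated
#' cheek.
#'
#' @param semi_axes ellipsoid semi-axes (x, y, z) in mm.
#' @param subdivision icosphere refinement level (default 4).
#' @param side operated hemiface, `"right"` (cheek at x < 0) or `"left"`.
#' @return a list: `mesh` (a `triangle_mesh`), `landmarks` (a
#'   `landmark_set`).
#' @export
generate_head <- function(semi_axes = c(70, 90, 100), subdivision = 4,
                          side = c("right", "left")) {
  side <- match.arg(side)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  sph <- icosphere(subdivision, radius = 1)
  mesh <- triangle_mesh(sweep(sph$vertices, 2, semi_axes, `*`), sph$faces)
  s <- if (side == "right") -1 else 1
  lms <- landmark_set(
    porion_left = c(-0.94 * a, 0, 0),
    porion_right = c(0.94 * a, 0, 0),
    orbitale_left = c(-0.43 * a, 0.85 * b, 0),
    nasion = c(0, 0.98 * b, 0.10 * cc),
    subnasale = c(0, 0.98 * b, -0.18 * cc),
    zygomatic_superior = c(s * 0.60 * a, 0.50 * b, 0.18 * cc),
    submandibular_inferior = c(s * 0.30 * a, 0.40 * b, -0.62 * cc),
    preauricular_posterior = c(s * 0.90 * a, -0.12 * b, -0.10 * cc),
    midline_anterior = c(0, 0.95 * b, -0.20 * cc),
    side = side)
  list(mesh = mesh, landmarks = lms)
}

#' Add a localized Gaussian swelling bump to a mesh
#'
#' Displaces every vertex along its outward area-weighted normal (computed
#' on the undeformed mesh) by `amplitude * exp(-d^2 / (2 sigma^2))`, where
#' `d` is the Euclidean distance from the vertex to `center`. The added
#' volume is measured by the generator's own oracle: the difference of
#' enclosed volumes (auto-closed) after versus before, at the generation
#' resolution.
#'
#' @param mesh a `triangle_mesh`.
#' @param center bump centre (mm), usually a point on the surface.
#' @param amplitude peak displacement (mm, >= 0).
#' @param sigma Gaussian width (mm, > 0).
#' @return a list: `mesh` (deformed), `added_volume` (mm^3).
#' @export
add_swelling_bump <- function(mesh, center, amplitude, sigma) {
  if (amplitude < 0) stop("bump amplitude must be >= 0")
  if (sigma <= 0) stop("bump sigma must be > 0")
  if (amplitude == 0)
    return(list(mesh = mesh, added_volume = 0))
  n <- vertex_normals(mesh)
  d2 <- rowSums(sweep(mesh$vertices, 2, as.numeric(center))^2)
  disp <- amplitude * exp(-d2 / (2 * sigma^2))
  out <- mesh
  out$vertices <- mesh$vertices + n * disp
  colnames(out$vertices) <- c("x", "y", "z")
  added <- volume_difference(out, mesh, auto_close = TRUE)
  list(mesh = out, added_volume = added)
}

#' Define a synthetic three-timepoint swelling scenario
#'
#' Describes the study conditions the generator emulates: a baseline head
#' scan (T0), a post-operative scan with a swelling bump on the operated
#' cheek (T1, three days), and a partially resolved scan (T2, one week,
#' amplitude no larger than T1's). Each scan is independently misaligned by
#' a seeded random rigid motion bounded by `rigid_noise`, standing in for
#' free-head scanner acquisition.
#'
#' @param semi_axes head ellipsoid semi-axes (mm).
#' @param subdivision mesh refinement level.
#' @param side operated hemiface.
#' @param bump_center bump centre (mm); default a mid-cheek surface point
#'   of the operated side.
#' @param bump_amplitude_T1 peak swelling at T1 (mm).
#' @param bump_amplitude_T2 residual swelling at T2 (mm, <= T1).
#' @param bump_sigma Gaussian width of the swelling (mm).
#' @param rigid_noise `c(max_rotation_deg, max_translation_mm)` per scan.
#' @param vertex_jitter_sd optional per-vertex Gaussian jitter (mm, default
#'   0 = off).
#' @param seed integer seed for all randomness.
#' @return a list of class `swelling_scenario`.
#' @export
swelling_scenario <- function(semi_axes = c(70, 90, 100), subdivision = 4,
                              side = "right",
                              bump_center = NULL,
                              bump_amplitude_T1 = 3,
                              bump_amplitude_T2 = 1,
                              bump_sigma = 15,
                              rigid_noise = c(5, 5),
                              vertex_jitter_sd = 0,
                              seed = 0L) {
  if (bump_amplitude_T1 < 0 || bump_amplitude_T2 < 0)
    stop("bump amplitudes must be >= 0")
  if (bump_amplitude_T2 > bump_amplitude_T1)
    stop("bump_amplitude_T2 must be <= bump_amplitude_T1 (swelling resolves)")
  if (bump_sigma <= 0) stop("bump_sigma must be > 0")
  if (is.null(bump_center)) {
    s <- if (identical(side, "right")) -1 else 1
    u <- c(s * 0.55, 0.55, -0.25)
    u <- u / sqrt(sum(u^2))
    bump_center <- u * as.numeric(semi_axes)
  }
  structure(list(semi_axes = as.numeric(semi_axes),
                 subdivision = as.integer(subdivision), side = side,
                 bump_center = as.numeric(bump_center),
                 bump_amplitude_T1 = bump_amplitude_T1,
                 bump_amplitude_T2 = bump_amplitude_T2,
                 bump_sigma = bump_sigma,
                 rigid_noise = as.numeric(rigid_noise),
                 vertex_jitter_sd = vertex_jitter_sd,
                 seed = as.integer(seed)),
            class = "swelling_scenario")
}

#' Generate a T0/T1/T2 scan triplet with known ground truth
#'
#' Builds T0 (baseline head), T1 (head plus the T1 bump) and T2 (head plus
#' the residual T2 bump), perturbs each by its own seeded rigid motion
#' within `rigid_noise`, and writes the meshes, the landmark file (in T0's
#' perturbed frame) and a ground-truth record. The ground truth carries the
#' generating transforms, the whole-head added volumes, and the added
#' volumes restricted to the analysis ROI (`analytic_added_volume_*`) —
#' the quantity the pipeline's ROI-based estimate is validated against —
#' all measured on the canonical-frame meshes before any misalignment.
#'
#' @param scenario a `swelling_scenario`.
#' @param out_dir output directory, created if needed; when NULL nothing is
#'   written and the objects are only returned.
#' @param mesh_format `"ply"` (default) or `"stl"` for the scan files.
#' @return (invisibly) a list with `meshes` (T0, T1, T2 as written),
#'   `landmarks` (T0 frame), `ground_truth`, and the file `paths`.
#' @export
make_scenario <- function(scenario, out_dir = NULL, mesh_format = "ply") {
  stopifnot(inherits(scenario, "swelling_scenario"))
  head <- generate_head(scenario$semi_axes, scenario$subdivision,
                        side = scenario$side)
  base <- head$mesh
  b1 <- add_swelling_bump(base, scenario$bump_center,
                          scenario$bump_amplitude_T1, scenario$bump_sigma)
  b2 <- add_swelling_bump(base, scenario$bump_center,
                          scenario$bump_amplitude_T2, scenario$bump_sigma)
  roi <- roi_from_landmarks(head$landmarks)
  vol_roi <- function(m) mesh_volume(clip_to_roi(m, roi), auto_close = TRUE)$volume
  v0 <- vol_roi(base); v1 <- vol_roi(b1$mesh); v2 <- vol_roi(b2$mesh)

  canonical <- list(T0 = base, T1 = b1$mesh, T2 = b2$mesh)
  transforms <- with_local_seed(scenario$seed, {
    lapply(1:3, function(i)
      random_rigid_transform(scenario$rigid_noise[1], scenario$rigid_noise[2]))
  })
  names(transforms) <- names(canonical)
  meshes <- canonical
  if (any(scenario$rigid_noise > 0)) {
    meshes <- mapply(apply_transform, canonical, transforms, SIMPLIFY = FALSE)
  }
  if (scenario$vertex_jitter_sd > 0) {
    meshes <- with_local_seed(scenario$seed + 1L, lapply(meshes, function(m) {
      m$vertices <- m$vertices +
        matrix(rnorm(length(m$vertices), sd = scenario$vertex_jitter_sd),
               ncol = 3)
      m
    }))
  }
  landmarks <- transform_landmarks(head$landmarks, transforms$T0)
  ground_truth <- list(
    transforms = lapply(transforms, function(t)
      list(rotation = unclass(t$rotation), translation = t$translation)),
    added_volume_total_T1 = b1$added_volume,
    added_volume_total_T2 = b2$added_volume,
    analytic_added_volume_T1 = v1 - v0,
    analytic_added_volume_T2 = v2 - v0,
    roi_volume_T0 = v0,
    bump_center = scenario$bump_center,
    bump_amplitude_T1 = scenario$bump_amplitude_T1,
    bump_amplitude_T2 = scenario$bump_amplitude_T2,
    bump_sigma = scenario$bump_sigma,
    seed = scenario$seed)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ext <- mesh_format
    paths <- list(
      t0 = file.path(out_dir, paste0("T0.", ext)),
      t1 = file.path(out_dir, paste0("T1.", ext)),
      t2 = file.path(out_dir, paste0("T2.", ext)),
      landmarks = file.path(out_dir, "landmarks.json"),
      ground_truth = file.path(out_dir, "ground_truth.json"))
    write_mesh(meshes$T0, paths$t0, format = mesh_format)
    write_mesh(meshes$T1, paths$t1, format = mesh_format)
    write_mesh(meshes$T2, paths$t2, format = mesh_format)
    write_landmarks(landmarks, paths$landmarks)
    writeLines(jsonlite::toJSON(ground_truth, digits = NA, auto_unbox = TRUE),
               paths$ground_truth)
  }
  invisible(list(meshes = meshes, landmarks = landmarks,
                 ground_truth = ground_truth, paths = paths,
                 canonical = canonical))
}
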
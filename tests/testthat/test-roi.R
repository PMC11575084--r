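test_that("the hemiface ROI is built from the four boundary landmarks", {
  lms <- landmark_set(
    zygomatic_superior = c(-40, 40, 40),
    submandibular_inferior = c(-20, 35, -40),
    preauricular_posterior = c(-60, -60, 0),
    midline_anterior = c(0, 80, -10),
    side = "right")
  roi <- roi_from_landmarks(lms)
  expect_length(roi$half_spaces, 4)
  inside <- points_in_roi(rbind(c(-10, 20, 0), c(10, 20, 0), c(-10, 20, 60)), roi)
  expect_identical(inside, c(TRUE, FALSE, FALSE))  # side=right keeps x <= 0
})

test_that("inconsistent superior/inferior landmarks are rejected", {
  lms <- landmark_set(
    zygomatic_superior = c(-40, 40, -50),
    submandibular_inferior = c(-20, 35, 40),
    preauricular_posterior = c(-60, -60, 0),
    midline_anterior = c(0, 80, -10),
    side = "right")
  expect_error(roi_from_landmarks(lms), "inconsistent ROI")
})

test_that("mirrored landmarks clip the mirror-image region", {
  mirror <- function(p) c(-p[1], p[2], p[3])
  base <- list(zygomatic_superior = c(-40, 40, 40),
               submandibular_inferior = c(-20, 35, -40),
               preauricular_posterior = c(-60, -60, 0),
               midline_anterior = c(0, 80, -10))
  roi_r <- roi_from_landmarks(landmark_set(points = base, side = "right"))
  roi_l <- roi_from_landmarks(landmark_set(points = lapply(base, mirror),
                                           side = "left"))
  set.seed(3)
  pts <- matrix(runif(300, -80, 80), ncol = 3)
  mpts <- pts; mpts[, 1] <- -mpts[, 1]
  expect_identical(points_in_roi(pts, roi_r), points_in_roi(mpts, roi_l))
})

test_that("clipping a unit cube through its middle leaves half the volume", {
  half <- clip_by_plane(unit_cube_mesh(), c(0.5, 0, 0), c(-1, 0, 0))
  expect_equal(mesh_volume(close_mesh(half))$volume, 0.5, tolerance = 1e-12)
})

test_that("an ROI containing the whole mesh returns it unchanged", {
  m <- icosphere(3, radius = 5)
  roi <- roi_spec(list(list(point = c(0, 0, -100), normal = c(0, 0, 1))))
  out <- clip_to_roi(m, roi)
  expect_identical(out$vertices, m$vertices)
  expect_identical(out$faces, m$faces)
})

test_that("clipping a sphere at the equator yields a hemisphere", {
  s <- icosphere(4, radius = 10)
  hemi <- clip_by_plane(s, c(0, 0, 0), c(0, 0, 1))
  expect_lt(abs(mesh_area(hemi) - 2 * pi * 100) / (2 * pi * 100), 0.01)
  expect_equal(diagnose_mesh(hemi)$n_boundary_loops, 1)
})

test_that("clipping is idempotent", {
  s <- icosphere(3, radius = 10)
  roi <- roi_spec(list(list(point = c(2, 0, 0), normal = c(-1, 0, 0)),
                       list(point = c(0, 0, -3), normal = c(0, 0, 1))))
  once <- clip_to_roi(s, roi)
  twice <- clip_to_roi(once, roi)
  c1 <- canonical_geometry(once); c2 <- canonical_geometry(twice)
  expect_equal(c2$vertices, c1$vertices, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(c2$faces, c1$faces, ignore_attr = TRUE)
})

test_that("a plane cut conserves total area across the two sides", {
  s <- random_star_mesh(11)
  a_all <- mesh_area(s)
  keep <- clip_by_plane(s, c(1, 0.5, 0), c(1, 2, 3))
  drop <- clip_by_plane(s, c(1, 0.5, 0), -c(1, 2, 3))
  expect_lt(abs(mesh_area(keep) + mesh_area(drop) - a_all) / a_all, 1e-6)
})

test_that("attributes interpolate linearly across the cut", {
  m <- grid_patch(10, 10, 11, 11)
  m$vertex_scalars$field <- m$vertices[, 1]  # scalar equal to x
  cut <- clip_by_plane(m, c(0.25, 0, 0), c(1, 0, 0))
  expect_equal(cut$vertex_scalars$field, unname(cut$vertices[, 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ROI JSON serialization round-trips", {
  roi <- roi_from_landmarks(generate_head()$landmarks)
  path <- withr::local_tempfile(fileext = ".json")
  roi_to_json(roi, path)
  back <- roi_from_json(path)
  expect_equal(length(back$half_spaces), length(roi$half_spaces))
  for (k in seq_along(roi$half_spaces)) {
    expect_equal(back$half_spaces[[k]]$normal, roi$half_spaces[[k]]$normal,
                 tolerance = 1e-12)
    expect_equal(back$half_spaces[[k]]$point, roi$half_spaces[[k]]$point,
                 tolerance = 1e-12)
  }
})
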
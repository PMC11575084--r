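test_that("the synthetic head has the refinement counts and ellipsoid volume", {
  gh <- generate_head(c(70, 90, 100), subdivision = 4)
  expect_equal(nrow(gh$mesh$vertices), 10 * 4^4 + 2)  # 2562
  expect_true(diagnose_mesh(gh$mesh)$is_watertight)
  analytic <- 4 / 3 * pi * 70 * 90 * 100
  expect_lt(abs(mesh_volume(gh$mesh)$volume - analytic) / analytic, 0.01)
  expect_error(generate_head(c(-1, 90, 100)), "positive")
})

test_that("generated landmarks already sit in the canonical frame", {
  gh <- generate_head()
  t <- orient_by_landmarks(gh$landmarks)
  expect_lt(max(abs(t$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(t$translation)), 1e-12)
  # and the ROI they define contains part of the head surface
  roi <- roi_from_landmarks(gh$landmarks)
  expect_gt(sum(points_in_roi(gh$mesh$vertices, roi)), 50)
})

test_that("a zero-amplitude bump is the identity with zero added volume", {
  gh <- generate_head(subdivision = 3)
  out <- add_swelling_bump(gh$mesh, c(-47, 59, -24), 0, 10)
  expect_identical(out$mesh$vertices, gh$mesh$vertices)
  expect_identical(out$added_volume, 0)
})

test_that("a centred Gaussian bump on a flat slab adds 2*pi*A*sigma^2", {
  patch <- grid_patch(100, 100, 101, 101)
  out <- add_swelling_bump(patch, c(0, 0, 0), amplitude = 2, sigma = 5)
  analytic <- 2 * pi * 2 * 5^2  # 314.159...
  expect_lt(abs(out$added_volume - analytic) / analytic, 0.02)
})

test_that("added volume increases strictly with amplitude", {
  gh <- generate_head(subdivision = 3)
  center <- swelling_scenario()$bump_center
  vols <- vapply(c(1, 2, 3), function(a)
    add_swelling_bump(gh$mesh, center, a, 15)$added_volume, 0)
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols > 0))
})

test_that("scenario generation is bit-identical under a fixed seed", {
  sc <- swelling_scenario(subdivision = 3, seed = 9L)
  a <- make_scenario(sc)
  b <- make_scenario(sc)
  expect_identical(a$meshes$T1$vertices, b$meshes$T1$vertices)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(unclass(a$landmarks), unclass(b$landmarks))
})

test_that("zero rigid noise leaves T0 exactly the base head", {
  sc <- swelling_scenario(subdivision = 3, rigid_noise = c(0, 0), seed = 4L)
  out <- make_scenario(sc)
  base <- generate_head(sc$semi_axes, sc$subdivision, side = sc$side)$mesh
  expect_identical(out$meshes$T0$vertices, base$vertices)
})

test_that("ground-truth added volumes follow the amplitude ordering", {
  sc <- swelling_scenario(subdivision = 3, bump_amplitude_T1 = 3,
                          bump_amplitude_T2 = 1, seed = 2L)
  gt <- make_scenario(sc)$ground_truth
  expect_gt(gt$analytic_added_volume_T1, gt$analytic_added_volume_T2)
  expect_gt(gt$analytic_added_volume_T2, 0)
  expect_gt(gt$added_volume_total_T1, gt$analytic_added_volume_T1)
  expect_error(swelling_scenario(bump_amplitude_T1 = 1, bump_amplitude_T2 = 2),
               "resolves")
})

test_that("scenario files land on disk and read back", {
  dir <- withr::local_tempdir()
  sc <- swelling_scenario(subdivision = 3, seed = 1L)
  out <- make_scenario(sc, out_dir = dir)
  expect_true(all(file.exists(unlist(out$paths))))
  t1 <- read_mesh(out$paths$t1)
  expect_equal(nrow(t1$vertices), nrow(out$meshes$T1$vertices))
  lms <- read_landmarks(out$paths$landmarks)
  expect_identical(attr(lms, "side"), "right")
})
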
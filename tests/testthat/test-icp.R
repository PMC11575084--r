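head_fixture <- generate_head()

test_that("registering a mesh onto itself returns the identity", {
  fit <- icp_register(head_fixture$mesh, head_fixture$mesh,
                      icp_params(subsample_size = 1000))
  expect_lt(fit$rms, 1e-8)
  expect_lt(max(abs(fit$transform$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(fit$transform$translation)), 1e-8)
})

test_that("trimmed ICP recovers seeded rigid motions below 0.1 mm", {
  for (s in 1:5) {
    set.seed(s)
    tr <- random_rigid_transform(10, 10)
    moved <- apply_transform(head_fixture$mesh, tr)
    fit <- suppressWarnings(
      icp_register(moved, head_fixture$mesh, icp_params(subsample_size = 2000)))
    expect_lt(mean_vertex_error(head_fixture$mesh, fit$transform, tr), 0.1)
  }
})

test_that("a swollen cheek is absorbed by trimming", {
  sc <- swelling_scenario()
  bumped <- add_swelling_bump(head_fixture$mesh, sc$bump_center, 3, 15)$mesh
  unswollen <- head_fixture$mesh$vertices[, 1] > 0  # bump sits at x < 0
  for (s in 1:3) {
    set.seed(100 + s)
    tr <- random_rigid_transform(10, 10)
    moved <- apply_transform(bumped, tr)
    fit <- suppressWarnings(
      icp_register(moved, head_fixture$mesh, icp_params(subsample_size = 2000)))
    v <- bumped$vertices
    w <- transform_points(v, compose_transforms(fit$transform, tr))
    err <- mean(sqrt(rowSums((w - v)^2))[unswollen])
    expect_lt(err, 0.5)
  }
})

test_that("ICP is deterministic given the seed and monotone on the trimmed set", {
  set.seed(77)
  tr <- random_rigid_transform(8, 8)
  moved <- apply_transform(head_fixture$mesh, tr)
  p <- icp_params(subsample_size = 1500, seed = 42L)
  f1 <- suppressWarnings(icp_register(moved, head_fixture$mesh, p))
  f2 <- suppressWarnings(icp_register(moved, head_fixture$mesh, p))
  expect_identical(f1$transform$rotation, f2$transform$rotation)
  expect_identical(f1$transform$translation, f2$transform$translation)
  expect_identical(f1$rms, f2$rms)
  expect_true(all(diff(f1$rms_history) <= 1e-9))
})

test_that("invalid inputs are rejected", {
  empty <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(icp_register(empty, head_fixture$mesh), "empty")
  expect_error(icp_params(trim_fraction = 0.6), "trim_fraction")
  expect_error(icp_params(rms_change_tolerance = 0), "tolerance")
})
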
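test_that("rigid transforms satisfy the group laws", {
  set.seed(1)
  for (k in 1:20) {
    t1 <- random_rigid_transform(30, 20)
    t2 <- random_rigid_transform(30, 20)
    inv <- compose_transforms(t1, invert_transform(t1))
    expect_lt(max(abs(inv$rotation - diag(3))), 1e-8)
    expect_lt(max(abs(inv$translation)), 1e-8)
    # associativity on a probe point
    p <- matrix(rnorm(3), 1)
    a <- transform_points(transform_points(p, t2), t1)
    b <- transform_points(p, compose_transforms(t1, t2))
    expect_equal(a, b, tolerance = 1e-10)
    expect_lt(abs(det(t1$rotation) - 1), 1e-8)
  }
})

test_that("applying a pure translation shifts the bounding box exactly", {
  m <- icosphere(2, radius = 4)
  t <- rigid_transform(diag(3), c(1, 2, 3))
  shifted <- apply_transform(m, t)
  expect_equal(diagnose_mesh(shifted)$bbox,
               diagnose_mesh(m)$bbox + rep(c(1, 2, 3), each = 2))
  expect_identical(apply_transform(m, identity_transform())$vertices,
                   m$vertices)
})

test_that("enclosed volume is invariant under rigid motion", {
  m <- icosphere(3, radius = 9)
  v0 <- mesh_volume(m)$volume
  set.seed(7)
  for (k in 1:5) {
    t <- random_rigid_transform(180, 50)
    v1 <- mesh_volume(apply_transform(m, t))$volume
    expect_lt(abs(v1 - v0) / v0, 1e-10)
  }
})

test_that("vector attributes rotate with the mesh", {
  m <- icosphere(1)
  m$vertex_vectors$displacement_mm <- matrix(rep(c(1, 0, 0), each = nrow(m$vertices)),
                                             ncol = 3)
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  t <- rigid_transform(R, c(0, 0, 0))
  out <- apply_transform(m, t)
  expect_equal(out$vertex_vectors$displacement_mm[1, ], c(0, 1, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the closed-form rigid fit recovers a known motion from noisy-free pairs", {
  set.seed(5)
  for (k in 1:10) {
    t <- random_rigid_transform(45, 30)
    p <- matrix(rnorm(60), ncol = 3)
    q <- transform_points(p, t)
    fit <- fit_rigid(p, q)
    expect_lt(max(abs(fit$rotation - t$rotation)), 1e-9)
    expect_lt(max(abs(fit$translation - t$translation)), 1e-9)
  }
})

test_that("transform JSON serialization round-trips", {
  set.seed(9)
  t <- random_rigid_transform(25, 12)
  path <- withr::local_tempfile(fileext = ".json")
  transform_to_json(t, path)
  back <- transform_from_json(path)
  expect_equal(back$rotation, t$rotation, tolerance = 1e-15)
  expect_equal(back$translation, t$translation, tolerance = 1e-15)
})
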
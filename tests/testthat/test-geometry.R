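test_that("closing a watertight mesh is the identity", {
  s <- icosphere(3, radius = 10)
  out <- close_mesh(s)
  expect_identical(out$vertices, s$vertices)
  expect_identical(out$faces, s$faces)
  expect_equal(attr(out, "n_holes_filled"), 0L)
})

test_that("a sphere with its polar cap removed closes watertight near the right volume", {
  s <- icosphere(4, radius = 10)
  open <- s
  zmax <- apply(matrix(s$vertices[s$faces, 3], ncol = 3), 1, min)
  open$faces <- s$faces[zmax < 9, , drop = FALSE]
  expect_equal(diagnose_mesh(open)$n_boundary_loops, 1)
  closed <- close_mesh(open)
  expect_true(diagnose_mesh(closed)$is_watertight)
  v <- mesh_volume(closed)$volume
  # independent rasterisation oracle at 0.2 mm
  expect_lt(abs(v - voxel_volume(closed, 0.2)) / v, 0.01)
})

test_that("an open tube closes both rims", {
  tube <- open_tube_mesh(24, radius = 5, height = 10)
  closed <- close_mesh(tube)
  expect_equal(attr(closed, "n_holes_filled"), 2L)
  expect_true(diagnose_mesh(closed)$is_watertight)
  # closed tube is a faceted cylinder; its volume has a closed form
  n <- 24
  analytic <- 0.5 * n * 25 * sin(2 * pi / n) * 10
  expect_equal(mesh_volume(closed)$volume, analytic, tolerance = 1e-9)
})

test_that("non-manifold edges raise a topology error naming the edge", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                           c(1, 1, 1)),
                     rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(close_mesh(m), "non-manifold edge \\(1, 2\\)")
})

test_that("the unit cube has exactly unit volume", {
  v <- mesh_volume(unit_cube_mesh())
  expect_identical(v$volume, 1)
  expect_false(v$orientation_flipped)
})

test_that("volume matches the tetrahedron-decomposition oracle to 1e-9", {
  for (s in 1:10) {
    m <- random_star_mesh(s)
    v <- mesh_volume(m)$volume
    expect_lt(abs(v - tet_volume_oracle(m)) / v, 1e-9)
  }
})

test_that("reversed winding gives the same volume and is flagged", {
  m <- icosphere(3, radius = 6)
  rev <- m
  rev$faces <- m$faces[, c(1, 3, 2)]
  a <- mesh_volume(m); b <- mesh_volume(rev)
  expect_equal(b$volume, a$volume, tolerance = 1e-15)
  expect_true(b$orientation_flipped)
  expect_false(a$orientation_flipped)
})

test_that("open meshes error without auto_close and close with it", {
  tube <- open_tube_mesh()
  expect_error(mesh_volume(tube), "2 boundary loop")
  v <- mesh_volume(tube, auto_close = TRUE)
  expect_true(v$was_closed_automatically)
  expect_equal(v$n_holes_filled, 2L)
})

test_that("volume differences: concentric shells, antisymmetry, zero identity", {
  a <- icosphere(4, radius = 51)
  b <- icosphere(4, radius = 50)
  shell <- 4 / 3 * pi * (51^3 - 50^3)
  expect_lt(abs(volume_difference(a, b) - shell) / shell, 0.01)
  expect_identical(volume_difference(a, b), -volume_difference(b, a))
  expect_identical(volume_difference(a, a), 0)
})

test_that("volume scales as the cube of uniform scaling and survives reindexing", {
  m <- random_star_mesh(4)
  v <- mesh_volume(m)$volume
  for (s in c(0.5, 2, 3.7)) {
    ms <- m; ms$vertices <- m$vertices * s
    expect_lt(abs(mesh_volume(ms)$volume - s^3 * v) / (s^3 * v), 1e-9)
  }
  set.seed(12)
  r <- reindex_mesh(m, vperm = sample(nrow(m$vertices)),
                    forder = sample(nrow(m$faces)))
  expect_lt(abs(mesh_volume(r)$volume - v) / v, 1e-12)
})

test_that("random hole patterns always close watertight", {
  for (s in 1:12) {
    m <- punch_holes(icosphere(3, radius = 10), k = 1 + s %% 4, seed = s)
    closed <- close_mesh(m)
    expect_true(diagnose_mesh(closed)$is_watertight)
  }
})
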
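test_that("the field of a mesh against itself is zero", {
  m <- icosphere(3, radius = 20)
  f <- signed_distance_field(m, m)
  expect_lt(max(abs(f$signed_distance)), 1e-9)
  expect_lt(max(abs(f$displacement)), 1e-9)
})

test_that("concentric spheres give a +1 mm field, role swap flips the sign", {
  inner <- icosphere(4, radius = 50)
  outer <- icosphere(4, radius = 51)
  f <- signed_distance_field(outer, inner)
  expect_true(all(f$signed_distance > 0))
  expect_lt(max(abs(f$signed_distance - 1)), 0.01)
  g <- signed_distance_field(inner, outer)
  expect_true(all(g$signed_distance < 0))
  expect_lt(max(abs(g$signed_distance + 1)), 0.02 * 1)  # within discretization
  # magnitude equals displacement norm, per vertex
  expect_lt(max(abs(abs(f$signed_distance) -
                    sqrt(rowSums(f$displacement^2)))), 1e-9)
})

test_that("a plane below the reference plane reads -2 mm in the interior", {
  compared <- grid_patch(40, 40, 21, 21)              # z = 0
  reference <- grid_patch(40, 40, 21, 21)
  reference$vertices[, 3] <- 2                        # z = 2, normals +z
  f <- signed_distance_field(compared, reference)
  interior <- abs(compared$vertices[, 1]) < 15 & abs(compared$vertices[, 2]) < 15
  expect_equal(unname(f$signed_distance[interior]),
               rep(-2, sum(interior)), tolerance = 1e-12)
})

test_that("the ROI mean is the plain signed average and needs vertices inside", {
  m <- icosphere(2, radius = 10)
  f <- signed_distance_field(m, m)
  f$signed_distance[] <- 1.6
  expect_equal(as.numeric(mean_linear_difference(f)), 1.6)
  half <- rep(c(2, -2), length.out = length(f$signed_distance))
  f$signed_distance <- half
  expect_equal(as.numeric(mean_linear_difference(f)), 0)
  far <- roi_spec(list(list(point = c(0, 0, 1000), normal = c(0, 0, 1))))
  expect_error(mean_linear_difference(f, far), "empty ROI")
})

test_that("the ROI mean ignores vertex order", {
  m <- icosphere(3, radius = 10)
  ref <- icosphere(3, radius = 9)
  f <- signed_distance_field(m, ref)
  roi <- roi_spec(list(list(point = c(0, 0, 0), normal = c(0, 0, 1))))
  m1 <- mean_linear_difference(f, roi)
  set.seed(8)
  perm <- sample(nrow(m$vertices))
  r <- reindex_mesh(f$mesh, vperm = perm)
  # reindexing carries the scalar with its vertex
  f2 <- structure(list(mesh = r,
                       signed_distance = r$vertex_scalars$signed_distance_mm,
                       displacement = r$vertex_vectors$displacement_mm,
                       pair_label = f$pair_label),
                  class = "distance_field")
  expect_equal(as.numeric(mean_linear_difference(f2, roi)), as.numeric(m1),
               tolerance = 1e-12)
})

test_that("co-transforming both surfaces leaves the field unchanged", {
  m <- add_swelling_bump(generate_head(subdivision = 3)$mesh,
                         c(-47, 59, -24), 2, 15)$mesh
  ref <- generate_head(subdivision = 3)$mesh
  f0 <- signed_distance_field(m, ref)
  set.seed(21)
  t <- random_rigid_transform(30, 20)
  f1 <- signed_distance_field(apply_transform(m, t), apply_transform(ref, t))
  expect_lt(max(abs(f1$signed_distance - f0$signed_distance)), 1e-6)
})

test_that("the diverging colormap hits its endpoints, midpoint and clamps", {
  cols <- diverging_color(c(2, 0, -2, -4, 4), span = 2)
  expect_equal(cols[1, ], c(red = 255L, green = 0L, blue = 0L))
  expect_equal(cols[2, ], c(red = 255L, green = 255L, blue = 255L))
  expect_equal(cols[3, ], c(red = 0L, green = 0L, blue = 255L))
  expect_equal(cols[4, ], cols[3, ])  # clamped at -2 * span
  expect_equal(cols[5, ], cols[1, ])
})

test_that("colormap export writes colours and the distance scalar to PLY", {
  m <- icosphere(2, radius = 10)
  f <- signed_distance_field(icosphere(2, radius = 11), m)
  path <- withr::local_tempfile(fileext = ".ply")
  colormap_export(f, path, span = 1)
  back <- read_mesh(path)
  expect_true(all(c("red", "green", "blue", "signed_distance_mm") %in%
                  names(back$vertex_scalars)))
  expect_true(all(back$vertex_scalars$red == 255))  # all at +span: pure red
  expect_true(all(back$vertex_scalars$blue == 0))
  expect_error(colormap_export(f, withr::local_tempfile(fileext = ".stl")),
               "STL")
})

test_that("displacement vectors export every stride-th vertex", {
  m <- icosphere(2, radius = 10)
  f <- signed_distance_field(icosphere(2, radius = 12), m)
  p1 <- withr::local_tempfile(fileext = ".vtk")
  displacement_vector_export(f, p1, stride = 1)
  back <- read_vtk_points <- read_mesh(p1)
  expect_equal(nrow(back$vertices), nrow(f$mesh$vertices))
  p3 <- withr::local_tempfile(fileext = ".vtk")
  displacement_vector_export(f, p3, stride = 3)
  back3 <- read_mesh(p3)
  expect_equal(nrow(back3$vertices),
               length(seq(1, nrow(f$mesh$vertices), by = 3)))
  # inflation field points radially outward
  v <- back$vertices
  d <- back$vertex_vectors$displacement_mm
  cosang <- rowSums(v * d) / (sqrt(rowSums(v^2)) * sqrt(rowSums(d^2)))
  expect_true(all(cosang > cos(5 * pi / 180)))
})
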
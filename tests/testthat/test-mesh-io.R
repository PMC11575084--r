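test_that("ASCII STL of a unit cube merges duplicate corners to 8 vertices", {
  path <- withr::local_tempfile(fileext = ".stl")
  ascii_stl_cube(path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_true(diagnose_mesh(m)$is_watertight)
})

test_that("binary STL of a subdivision-3 icosphere keeps the refinement counts", {
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(icosphere(3, radius = 10), path, format = "stl", binary = TRUE)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 10 * 4^3 + 2)  # 642
  expect_equal(nrow(m$faces), 20 * 4^3)         # 1280
})

test_that("write/read round-trips preserve geometry for every format", {
  m <- icosphere(2, radius = 7.3, center = c(1, -2, 3))
  for (spec in list(list(fmt = "ply", bin = FALSE), list(fmt = "ply", bin = TRUE),
                    list(fmt = "vtk", bin = FALSE),
                    list(fmt = "stl", bin = FALSE), list(fmt = "stl", bin = TRUE))) {
    path <- withr::local_tempfile(fileext = paste0(".", spec$fmt))
    write_mesh(m, path, binary = spec$bin)
    back <- read_mesh(path)
    ca <- canonical_geometry(m); cb <- canonical_geometry(back)
    tol <- if (spec$fmt == "stl") 1e-6 else 1e-12  # STL stores float32
    expect_equal(cb$vertices, ca$vertices, tolerance = tol,
                 ignore_attr = TRUE)
    expect_equal(nrow(cb$faces), nrow(ca$faces))
  }
})

test_that("PLY and VTK preserve vertex scalars and vectors, PLY bit-exactly", {
  m <- icosphere(1, radius = 5)
  m$vertex_scalars$signed_distance_mm <- sin(seq_len(nrow(m$vertices)))
  m$vertex_vectors$displacement_mm <- m$vertices * 0.1
  for (fmt in c("ply", "vtk")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    back <- read_mesh(path)
    expect_identical(back$vertex_scalars$signed_distance_mm,
                     m$vertex_scalars$signed_distance_mm)
    expect_identical(unname(back$vertex_vectors$displacement_mm),
                     unname(m$vertex_vectors$displacement_mm))
  }
  # binary little-endian PLY too
  pathb <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, pathb, binary = TRUE)
  backb <- read_mesh(pathb)
  expect_identical(backb$vertex_scalars$signed_distance_mm,
                   m$vertex_scalars$signed_distance_mm)
})

test_that("STL refuses attributes unless explicitly dropped", {
  m <- icosphere(1)
  m$vertex_scalars$signed_distance_mm <- rep(1, nrow(m$vertices))
  path <- withr::local_tempfile(fileext = ".stl")
  expect_error(write_mesh(m, path), "drop_attributes")
  write_mesh(m, path, drop_attributes = TRUE)
  back <- read_mesh(path)
  expect_length(back$vertex_scalars, 0)
})

test_that("unreadable or malformed files raise located format errors", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid junk", " facet normal 0 0 1", "  outer loop",
               "   vertex 0 0 oops"), path)
  expect_error(read_mesh(path), "line")
  expect_error(read_mesh(file.path(tempdir(), "nope.ply")), "exist")
  vpath <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "t", "ASCII", "DATASET POLYDATA",
               "POINTS 4 double", "0 0 0 1 0 0 0 1 0 0 0 1",
               "POLYGONS 1 5", "4 0 1 2 3"), vpath)
  expect_error(read_mesh(vpath), "topology")
})

test_that("anonymize empties metadata and colour but never touches geometry", {
  m <- icosphere(1)
  m$metadata <- list(patient = "X", scanner = "ACME-3000")
  m$vertex_scalars$red <- rep(10, nrow(m$vertices))
  m$vertex_scalars$signed_distance_mm <- rep(0.5, nrow(m$vertices))
  a <- anonymize_mesh(m)
  expect_length(a$metadata, 0)
  expect_null(a$vertex_scalars$red)
  expect_identical(a$vertex_scalars$signed_distance_mm,
                   m$vertex_scalars$signed_distance_mm)
  expect_identical(a$vertices, m$vertices)
  expect_identical(a$faces, m$faces)
})

test_that("diagnostics count boundary loops and detect watertightness", {
  s <- icosphere(2, radius = 10)
  d <- diagnose_mesh(s)
  expect_equal(d$n_boundary_loops, 0)
  expect_true(d$is_watertight)
  expect_true(d$is_consistently_oriented)

  hole1 <- s
  hole1$faces <- s$faces[rowSums(matrix(s$faces == 1L, ncol = 3)) == 0, ]
  d1 <- diagnose_mesh(hole1)
  expect_equal(d1$n_boundary_loops, 1)
  expect_false(d1$is_watertight)

  expect_equal(diagnose_mesh(open_tube_mesh())$n_boundary_loops, 2)
})

test_that("diagnostics are invariant under vertex and face reindexing", {
  s <- icosphere(2)
  set.seed(42)
  r <- reindex_mesh(s, vperm = sample(nrow(s$vertices)),
                    forder = sample(nrow(s$faces)))
  d0 <- diagnose_mesh(s); d1 <- diagnose_mesh(r)
  expect_equal(d1$n_boundary_loops, d0$n_boundary_loops)
  expect_equal(d1$is_watertight, d0$is_watertight)
  expect_equal(d1$n_faces, d0$n_faces)
})
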
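# Fixtures are built in code; nothing is read from disk.

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0, outward -z
             c(5, 6, 8), c(5, 8, 7),   # z = 1
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = 1
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = 1
  triangle_mesh(v, f)
}

# ASCII STL text for the unit cube, duplicated corners as scanners export
ascii_stl_cube <- function(path) {
  m <- unit_cube_mesh()
  write_mesh(m, path, format = "stl", binary = FALSE)
  path
}

# open tube: two rings of n vertices, 2n side triangles, 2 boundary loops
open_tube_mesh <- function(n = 16, radius = 5, height = 10) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  v <- rbind(cbind(radius * cos(th), radius * sin(th), 0),
             cbind(radius * cos(th), radius * sin(th), height))
  i <- seq_len(n); j <- c(seq_len(n - 1) + 1, 1)
  f <- rbind(cbind(i, j, j + n), cbind(i, j + n, i + n))
  triangle_mesh(v, f)
}

# independent volume oracle: signed tetrahedra against an interior point
tet_volume_oracle <- function(mesh) {
  p <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2, p)
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))) / 6
}

# random smooth star-shaped watertight mesh (radial field on an icosphere)
random_star_mesh <- function(seed, subdivision = 3) {
  set.seed(seed)
  s <- icosphere(subdivision, radius = 1)
  u <- s$vertices
  co <- runif(6, -0.2, 0.2)
  r <- 10 * (1 + co[1] * u[, 1] * u[, 2] + co[2] * u[, 2] * u[, 3] +
               co[3] * u[, 1] * u[, 3] + co[4] * (u[, 1]^2 - u[, 3]^2) +
               co[5] * sin(2 * u[, 1]) + co[6] * cos(2 * u[, 2] + u[, 3]))
  triangle_mesh(u * r, s$faces)
}

# delete all faces incident to k random vertices -> k (possibly merging) holes
punch_holes <- function(mesh, k, seed) {
  set.seed(seed)
  vs <- sample.int(nrow(mesh$vertices), k)
  hit <- matrix(mesh$faces %in% vs, ncol = 3)
  mesh$faces <- mesh$faces[rowSums(hit) == 0, , drop = FALSE]
  mesh
}

mean_vertex_error <- function(mesh, recovered, generating) {
  v <- mesh$vertices
  w <- transform_points(v, compose_transforms(recovered, generating))
  mean(sqrt(rowSums((w - v)^2)))
}

# canonical form for comparing meshes up to vertex/face reordering
canonical_geometry <- function(mesh) {
  v <- mesh$vertices
  key <- paste(sprintf("%.12g", v[, 1]), sprintf("%.12g", v[, 2]),
               sprintf("%.12g", v[, 3]))
  ord <- order(key)
  remap <- integer(nrow(v)); remap[ord] <- seq_len(nrow(v))
  f <- matrix(remap[mesh$faces], ncol = 3)
  f <- t(apply(f, 1, function(r) {  # rotate each face to start at min index
    i <- which.min(r); r[c(i:3, seq_len(i - 1))[1:3]]
  }))
  f <- f[order(f[, 1], f[, 2], f[, 3]), , drop = FALSE]
  list(vertices = v[ord, , drop = FALSE], faces = f)
}
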
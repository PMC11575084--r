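#' Read a triangle mesh from STL, PLY or legacy VTK polydata
#'
#' STL (ASCII and binary) stores per-facet corners; duplicate corners are
#' merged by exact coordinate equality, so scanner exports that repeat
#' corners bit-identically collapse to an indexed mesh. PLY (ASCII and
#' binary little-endian) and legacy VTK polydata ASCII carry per-vertex
#' scalar and vector attributes, which are preserved.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"stl"`, `"ply"`, `"vtk"`. `"auto"`
#'   detects from the file extension, falling back to content sniffing.
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- switch(ext, stl = "stl", ply = "ply", vtk = "vtk", {
      head <- readBin(path, "raw", 16)
      txt <- rawToChar(head[head != as.raw(0)])
      if (grepl("^ply", txt)) "ply"
      else if (grepl("^# vtk", txt)) "vtk"
      else "stl"
    })
  }
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         vtk = read_vtk_polydata(path))
}

#' Write a triangle mesh to STL, PLY or legacy VTK polydata
#'
#' STL carries geometry only: writing a mesh that holds vertex attributes
#' raises a capability error unless `drop_attributes = TRUE`. PLY and VTK
#' polydata preserve `vertex_scalars` and `vertex_vectors`; PLY additionally
#' persists the metadata block as header comments.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @param format `"auto"` (from extension), `"stl"`, `"ply"` or `"vtk"`.
#' @param binary write the binary dialect where the format has one
#'   (binary STL, binary little-endian PLY). VTK polydata is always ASCII.
#' @param drop_attributes silently drop attributes unsupported by the format.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "vtk"),
                       binary = FALSE, drop_attributes = FALSE) {
  mesh_validate(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- switch(ext, stl = "stl", ply = "ply", vtk = "vtk",
                     stop("cannot infer mesh format from extension '.", ext, "'"))
  }
  has_attr <- length(mesh$vertex_scalars) > 0 || length(mesh$vertex_vectors) > 0
  if (format == "stl" && has_attr && !drop_attributes)
    stop("STL cannot carry vertex attributes; set drop_attributes = TRUE ",
         "to write geometry only")
  switch(format,
         stl = if (binary) write_stl_binary(mesh, path) else
           write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path, binary = binary),
         vtk = write_vtk_polydata(mesh, path))
  invisible(path)
}

fmt_g <- function(x) sprintf("%.17g", x)

merge_duplicate_vertices <- function(corners, nfacets) {
  key <- paste(fmt_g(corners[, 1]), fmt_g(corners[, 2]), fmt_g(corners[, 3]))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  verts <- corners[first, , drop = FALSE]
  faces <- matrix(idx, nrow = nfacets, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

# ---------------------------------------------------------------- STL ----

stl_is_ascii <- function(path) {
  sz <- file.info(path)$size
  head <- readBin(path, "raw", min(512, sz))
  printable <- head[head >= as.raw(32) & head < as.raw(127)]
  txt <- tolower(rawToChar(printable))
  startsWith(txt, "solid") && grepl("facet", txt)
}

read_stl <- function(path) {
  if (stl_is_ascii(path)) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vidx <- grep("^\\s*vertex\\b", lines)
  if (length(vidx) == 0)
    stop("STL parse error in ", path, ": no 'vertex' records found (line 1)")
  if (length(vidx) %% 3 != 0)
    stop("STL parse error in ", path, ": vertex count ", length(vidx),
         " not a multiple of 3 (near line ", vidx[length(vidx)], ")")
  nums <- lapply(vidx, function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
    x <- suppressWarnings(as.numeric(parts))
    if (length(x) != 3 || anyNA(x))
      stop("STL parse error in ", path, " at line ", i, ": '", lines[i], "'")
    x
  })
  corners <- do.call(rbind, nums)
  mf <- merge_duplicate_vertices(corners, length(vidx) / 3)
  triangle_mesh(mf$vertices, mf$faces)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(n) || n < 0 || sz < 84 + 50 * as.numeric(n))
    stop("STL parse error in ", path, ": facet count ", n,
         " inconsistent with file size ", sz, " (byte offset 80)")
  payload <- readBin(con, "raw", 50 * n)
  fidx <- as.vector(outer(1:48, (0:(n - 1)) * 50, "+"))
  floats <- readBin(payload[fidx], "numeric", n = 12 * n, size = 4,
                    endian = "little")
  m <- matrix(floats, nrow = n, byrow = TRUE)
  # interleave the three corner blocks back to per-facet order
  corners <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                   m[, 10:12, drop = FALSE])
  corners <- corners[as.vector(t(matrix(seq_len(3 * n), ncol = 3))), , drop = FALSE]
  mf <- merge_duplicate_vertices(corners, n)
  triangle_mesh(mf$vertices, mf$faces)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid swellkit", con)
  block <- paste0(" facet normal ", fmt_g(n[, 1]), " ", fmt_g(n[, 2]), " ",
                  fmt_g(n[, 3]), "\n  outer loop\n",
                  "   vertex ", fmt_g(a[, 1]), " ", fmt_g(a[, 2]), " ", fmt_g(a[, 3]), "\n",
                  "   vertex ", fmt_g(b[, 1]), " ", fmt_g(b[, 2]), " ", fmt_g(b[, 3]), "\n",
                  "   vertex ", fmt_g(cc[, 1]), " ", fmt_g(cc[, 2]), " ", fmt_g(cc[, 3]), "\n",
                  "  endloop\n endfacet")
  writeLines(block, con)
  writeLines("endsolid swellkit", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "swellkit binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  dat <- t(cbind(n, a, b, cc))  # 12 floats per facet, facet-major
  floats <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
  fm <- matrix(floats, nrow = 48)
  rec <- rbind(fm, matrix(as.raw(0), nrow = 2, ncol = nf))
  writeBin(as.vector(rec), con)
}

# ---------------------------------------------------------------- PLY ----

ply_scalar_order <- function(mesh) {
  names(mesh$vertex_scalars)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0 || ch == as.raw(10)) break
      if (ch != as.raw(13)) chars <- c(chars, ch)
    }
    rawToChar(chars)
  }
  if (read_hline() != "ply") stop("PLY parse error in ", path, ": missing 'ply' magic (line 1)")
  fmt <- NULL; elements <- list(); cur <- NULL; metadata <- list()
  lineno <- 1
  repeat {
    ln <- read_hline(); lineno <- lineno + 1
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("PLY parse error in ", path, ": unsupported format '", fmt,
             "' (line ", lineno, ")")
    } else if (tok[1] == "comment") {
      kv <- sub("^comment\\s+", "", ln)
      if (grepl("=", kv)) {
        k <- sub("=.*", "", kv); val <- sub("^[^=]*=", "", kv)
        metadata[[k]] <- val
      }
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE,
                                                count_type = tok[3],
                                                item_type = tok[4])
      } else {
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") break
    else if (tok[1] == "obj_info") next
    else stop("PLY parse error in ", path, ": unexpected header line ",
              lineno, ": '", ln, "'")
  }
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_typed <- function(bytes, type, n) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(bytes, "numeric", n = n, size = sz, endian = "little")
    else if (type %in% c("uchar", "uint8"))
      as.numeric(readBin(bytes, "integer", n = n, size = 1, signed = FALSE,
                         endian = "little"))
    else
      as.numeric(readBin(bytes, "integer", n = n, size = sz,
                         signed = !(type %in% c("ushort", "uint16")),
                         endian = "little"))
  }
  vals <- list()
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    pos <- 1
    for (en in names(elements)) {
      el <- elements[[en]]
      if (el$n == 0) { vals[[en]] <- list(); next }
      block <- rest[pos:(pos + el$n - 1)]; pos <- pos + el$n
      tokmat <- strsplit(trimws(block), "\\s+")
      if (en == "face" || any(vapply(el$props, `[[`, TRUE, "list"))) {
        cnts <- as.integer(vapply(tokmat, `[[`, "", 1))
        if (any(cnts != 3))
          stop("unsupported topology in ", path, ": non-triangular face with ",
               max(cnts), " vertices")
        idx <- t(vapply(tokmat, function(tk) as.integer(tk[2:4]), integer(3)))
        vals[[en]] <- list(face_index = idx)
      } else {
        m <- t(vapply(tokmat, function(tk) as.numeric(tk), numeric(length(el$props))))
        colnames(m) <- names(el$props)
        vals[[en]] <- as.list(as.data.frame(m))
      }
    }
  } else {
    payload <- readBin(con, "raw", file.info(path)$size)
    off <- 0
    for (en in names(elements)) {
      el <- elements[[en]]
      is_list <- vapply(el$props, `[[`, TRUE, "list")
      if (!any(is_list)) {
        sizes <- vapply(names(el$props), function(p) type_size[[el$props[[p]]$type]], 1)
        stride <- sum(sizes)
        starts <- cumsum(c(0, sizes[-length(sizes)]))
        out <- list()
        for (k in seq_along(el$props)) {
          p <- names(el$props)[k]
          bidx <- as.vector(outer(seq_len(sizes[k]),
                                  off + (0:(el$n - 1)) * stride + starts[k], "+"))
          out[[p]] <- read_typed(payload[bidx], el$props[[p]]$type, el$n)
        }
        vals[[en]] <- out
        off <- off + el$n * stride
      } else {
        pr <- el$props[[which(is_list)[1]]]
        csz <- type_size[[pr$count_type]]; isz <- type_size[[pr$item_type]]
        first_cnt <- read_typed(payload[off + seq_len(csz)], pr$count_type, 1)
        if (first_cnt != 3)
          stop("unsupported topology in ", path, ": non-triangular face with ",
               first_cnt, " vertices")
        stride <- csz + 3 * isz
        cidx <- off + (0:(el$n - 1)) * stride
        cnts <- read_typed(payload[as.vector(outer(seq_len(csz), cidx, "+"))],
                           pr$count_type, el$n)
        if (any(cnts != 3))
          stop("unsupported topology in ", path, ": non-triangular face")
        iidx <- as.vector(outer(seq_len(3 * isz), cidx + csz, "+"))
        idx <- matrix(read_typed(payload[iidx], pr$item_type, 3 * el$n),
                      ncol = 3, byrow = TRUE)
        vals[[en]] <- list(face_index = idx)
        off <- off + el$n * stride
      }
    }
  }
  vprops <- vals[["vertex"]]
  if (is.null(vprops) || is.null(vprops$x))
    stop("PLY parse error in ", path, ": no vertex x/y/z properties")
  verts <- cbind(vprops$x, vprops$y, vprops$z)
  faces <- vals[["face"]]$face_index
  if (is.null(faces)) faces <- matrix(integer(0), 0, 3)
  scalars <- list(); vectors <- list()
  other <- setdiff(names(vprops), c("x", "y", "z"))
  vec_bases <- unique(sub("_[xyz]$", "", other[grepl("_[xyz]$", other)]))
  vec_bases <- vec_bases[vapply(vec_bases, function(b)
    all(paste0(b, c("_x", "_y", "_z")) %in% other), TRUE)]
  for (b in vec_bases) {
    vectors[[b]] <- cbind(vprops[[paste0(b, "_x")]],
                          vprops[[paste0(b, "_y")]],
                          vprops[[paste0(b, "_z")]])
    other <- setdiff(other, paste0(b, c("_x", "_y", "_z")))
  }
  for (p in other) scalars[[p]] <- vprops[[p]]
  triangle_mesh(verts, faces + 1L, vertex_scalars = scalars,
                vertex_vectors = vectors, metadata = metadata)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  scalars <- mesh$vertex_scalars
  vectors <- mesh$vertex_vectors
  color_names <- intersect(c("red", "green", "blue"), names(scalars))
  header <- c("ply",
              paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
              "comment written by swellkit")
  for (k in names(mesh$metadata))
    header <- c(header, paste0("comment ", k, "=", mesh$metadata[[k]]))
  header <- c(header, paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z")
  for (s in setdiff(names(scalars), color_names))
    header <- c(header, paste("property double", s))
  for (s in color_names)
    header <- c(header, paste("property uchar", s))
  for (b in names(vectors))
    header <- c(header, paste0("property double ", b, c("_x", "_y", "_z")))
  header <- c(header, paste("element face", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  cols <- list(v[, 1], v[, 2], v[, 3])
  types <- c("d", "d", "d")
  for (s in setdiff(names(scalars), color_names)) {
    cols <- c(cols, list(scalars[[s]])); types <- c(types, "d")
  }
  for (s in color_names) {
    cols <- c(cols, list(scalars[[s]])); types <- c(types, "u")
  }
  for (b in names(vectors)) {
    cols <- c(cols, list(vectors[[b]][, 1], vectors[[b]][, 2], vectors[[b]][, 3]))
    types <- c(types, "d", "d", "d")
  }
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    nv <- nrow(v)
    sizes <- ifelse(types == "d", 8L, 1L)
    stride <- sum(sizes)
    rec <- matrix(as.raw(0), nrow = stride, ncol = nv)
    starts <- cumsum(c(0L, sizes[-length(sizes)]))
    for (k in seq_along(cols)) {
      if (types[k] == "d")
        bytes <- writeBin(as.numeric(cols[[k]]), raw(), size = 8, endian = "little")
      else
        bytes <- writeBin(as.integer(round(cols[[k]])), raw(), size = 1,
                          endian = "little")
      bm <- matrix(bytes, nrow = sizes[k])
      rec[starts[k] + seq_len(sizes[k]), ] <- bm
    }
    writeBin(as.vector(rec), con)
    if (nrow(f) > 0) {
      fidx <- writeBin(as.integer(t(f) - 1L), raw(), size = 4, endian = "little")
      fm <- matrix(fidx, nrow = 12)
      frec <- rbind(matrix(as.raw(3), 1, nrow(f)), fm)
      writeBin(as.vector(frec), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    strs <- lapply(seq_along(cols), function(k)
      if (types[k] == "d") fmt_g(cols[[k]]) else
        as.character(as.integer(round(cols[[k]]))))
    writeLines(do.call(paste, strs), con)
    if (nrow(f) > 0)
      writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

# ---------------------------------------------------- VTK polydata -------

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk", lines[1]))
    stop("VTK parse error in ", path, ": missing '# vtk' magic (line 1)")
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("VTK parse error in ", path, ": only ASCII legacy files supported (line 3)")
  if (!grepl("POLYDATA", lines[4]))
    stop("VTK parse error in ", path, ": DATASET is not POLYDATA (line 4)")
  i <- 5
  nums_after <- function(start, count) {
    # read `count` numbers beginning at line `start`; return values and next line
    acc <- numeric(0); j <- start
    while (length(acc) < count && j <= length(lines)) {
      acc <- c(acc, scan(text = lines[j], quiet = TRUE))
      j <- j + 1
    }
    if (length(acc) < count)
      stop("VTK parse error in ", path, ": truncated block at line ", j)
    list(values = acc[seq_len(count)], next_line = j)
  }
  verts <- NULL; faces <- matrix(integer(0), 0, 3)
  scalars <- list(); vectors <- list()
  npts <- 0
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1; next }
    tok <- strsplit(ln, "\\s+")[[1]]
    kw <- toupper(tok[1])
    if (kw == "POINTS") {
      npts <- as.integer(tok[2])
      r <- nums_after(i + 1, 3 * npts)
      verts <- matrix(r$values, ncol = 3, byrow = TRUE)
      i <- r$next_line
    } else if (kw == "POLYGONS") {
      ncells <- as.integer(tok[2]); ntot <- as.integer(tok[3])
      r <- nums_after(i + 1, ntot)
      vals <- as.integer(r$values)
      faces <- matrix(0L, ncells, 3); p <- 1
      for (cidx in seq_len(ncells)) {
        cnt <- vals[p]
        if (cnt != 3)
          stop("unsupported topology in ", path, ": polygon with ", cnt,
               " vertices (cell ", cidx, ")")
        faces[cidx, ] <- vals[(p + 1):(p + 3)] + 1L
        p <- p + cnt + 1
      }
      i <- r$next_line
    } else if (kw == "POINT_DATA") {
      i <- i + 1
    } else if (kw == "SCALARS") {
      nm <- tok[2]
      j <- i + 1
      if (grepl("^LOOKUP_TABLE", toupper(trimws(lines[j])))) j <- j + 1
      r <- nums_after(j, npts)
      scalars[[nm]] <- r$values
      i <- r$next_line
    } else if (kw == "VECTORS") {
      nm <- tok[2]
      r <- nums_after(i + 1, 3 * npts)
      vectors[[nm]] <- matrix(r$values, ncol = 3, byrow = TRUE)
      i <- r$next_line
    } else if (kw == "COLOR_SCALARS") {
      ncomp <- as.integer(tok[3])
      r <- nums_after(i + 1, ncomp * npts)
      m <- matrix(r$values, ncol = ncomp, byrow = TRUE)
      cn <- c("red", "green", "blue", "alpha")[seq_len(ncomp)]
      for (k in seq_len(ncomp)) scalars[[cn[k]]] <- round(m[, k] * 255)
      i <- r$next_line
    } else if (kw %in% c("VERTICES", "LINES")) {
      ntot <- as.integer(tok[3])
      r <- nums_after(i + 1, ntot)
      i <- r$next_line
    } else {
      i <- i + 1
    }
  }
  if (is.null(verts)) stop("VTK parse error in ", path, ": no POINTS block")
  triangle_mesh(verts, faces, vertex_scalars = scalars,
                vertex_vectors = vectors)
}

write_vtk_polydata <- function(mesh, path, extra_colors01 = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "swellkit mesh", "ASCII",
               "DATASET POLYDATA"), con)
  writeLines(paste("POINTS", nrow(v), "double"), con)
  writeLines(paste(fmt_g(v[, 1]), fmt_g(v[, 2]), fmt_g(v[, 3])), con)
  if (nrow(f) > 0) {
    writeLines(paste("POLYGONS", nrow(f), 4 * nrow(f)), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  has_pd <- length(mesh$vertex_scalars) > 0 || length(mesh$vertex_vectors) > 0 ||
    !is.null(extra_colors01)
  if (has_pd) {
    writeLines(paste("POINT_DATA", nrow(v)), con)
    for (s in names(mesh$vertex_scalars)) {
      writeLines(c(paste("SCALARS", s, "double 1"), "LOOKUP_TABLE default"), con)
      writeLines(fmt_g(mesh$vertex_scalars[[s]]), con)
    }
    for (b in names(mesh$vertex_vectors)) {
      writeLines(paste("VECTORS", b, "double"), con)
      vv <- mesh$vertex_vectors[[b]]
      writeLines(paste(fmt_g(vv[, 1]), fmt_g(vv[, 2]), fmt_g(vv[, 3])), con)
    }
    if (!is.null(extra_colors01)) {
      writeLines(paste("COLOR_SCALARS rgb", ncol(extra_colors01)), con)
      writeLines(apply(round(extra_colors01, 6), 1, paste, collapse = " "), con)
    }
  }
  invisible(path)
}
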
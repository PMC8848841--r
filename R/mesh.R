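# Triangle mesh container and I/O (PLY ascii / binary little-endian, STL
# binary). Vertices are an n x 3 double matrix in mm; faces an m x 3 integer
# matrix of 1-based vertex indices with counter-clockwise (outward) winding.

#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as_points(vertices)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) > 0L) {
    rng <- range(faces)
    if (rng[1L] < 1L || rng[2L] > nrow(vertices)) {
      stop("face indices out of range", call. = FALSE)
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat("trimesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh `trimesh`.
#' @param tf `rigid_transform`.
#' @return transformed `trimesh`.
#' @export
transform_mesh <- function(mesh, tf) {
  trimesh(apply_rigid(tf, mesh$vertices), mesh$faces)
}

# Undirected edge list (m*3 x 2, each row sorted) of a mesh.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Edge lengths of a mesh
#'
#' Each undirected edge contributes once. Useful as a rigid-motion
#' invariant: rigid poses of one body share the edge-length multiset.
#'
#' @param mesh `trimesh`.
#' @return sorted numeric vector of unique-edge lengths (mm).
#' @export
edge_lengths <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  d <- mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE]
  sort(sqrt(rowSums(d^2)))
}

mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Check that a mesh is closed and consistently wound
#'
#' A watertight orientable surface has every undirected edge shared by
#' exactly two faces, traversed once in each direction.
#'
#' @param mesh `trimesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key_dir <- paste(he[, 1L], he[, 2L])
  key_und <- paste(pmin(he[, 1L], he[, 2L]), pmax(he[, 1L], he[, 2L]))
  all(table(key_und) == 2L) && !anyDuplicated(key_dir)
}

#' Enclosed volume of a closed mesh
#'
#' Signed tetrahedron sum; positive for outward winding.
#'
#' @param mesh closed `trimesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  cr <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
              b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
              b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(rowSums(a * cr)) / 6
}

#' Surface area of a mesh
#'
#' @param mesh `trimesh`.
#' @return total triangle area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ab <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  ac <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

# Merge vertices that are bitwise identical; remap faces, drop degenerate
# faces that collapse onto fewer than 3 distinct vertices.
merge_duplicate_vertices <- function(vertices, faces) {
  key <- paste(vertices[, 1L], vertices[, 2L], vertices[, 3L])
  first <- !duplicated(key)
  newid <- match(key, key[first])
  faces2 <- matrix(newid[faces], ncol = 3L)
  keep <- faces2[, 1L] != faces2[, 2L] & faces2[, 2L] != faces2[, 3L] &
    faces2[, 1L] != faces2[, 3L]
  trimesh(vertices[first, , drop = FALSE], faces2[keep, , drop = FALSE])
}

# Connected components of faces through shared vertices.
# Returns an integer component label per face.
mesh_face_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1L]); b <- find(f[r, 2L]); c_ <- find(f[r, 3L])
    parent[b] <- a
    parent[c_] <- a
  }
  root <- vapply(f[, 1L], find, integer(1L))
  match(root, unique(root))
}

# Keep the faces in `keep` and drop now-unused vertices.
subset_mesh_faces <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(match(f, used), ncol = 3L))
}

# First intersection of the ray (origin, dir) with the mesh
# (Moller-Trumbore, vectorized over faces). Returns the hit point or NULL.
ray_mesh_intersect <- function(mesh, origin, dir, tmin = -1e-9) {
  v <- mesh$vertices; f <- mesh$faces
  d <- unitv(dir)
  v0 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - v0
  e2 <- v[f[, 3L], , drop = FALSE] - v0
  pv <- cbind(d[2L] * e2[, 3L] - d[3L] * e2[, 2L],
              d[3L] * e2[, 1L] - d[1L] * e2[, 3L],
              d[1L] * e2[, 2L] - d[2L] * e2[, 1L])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- sweep(-v0, 2L, as.numeric(origin), "+")
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2L] * e1[, 3L] - tv[, 3L] * e1[, 2L],
              tv[, 3L] * e1[, 1L] - tv[, 1L] * e1[, 3L],
              tv[, 1L] * e1[, 2L] - tv[, 2L] * e1[, 1L])
  vv <- (qv[, 1L] * d[1L] + qv[, 2L] * d[2L] + qv[, 3L] * d[3L]) / det
  tt <- rowSums(e2 * qv) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt >= tmin
  if (!any(hit)) return(NULL)
  tbest <- min(tt[hit])
  as.numeric(origin + tbest * d)
}

## ---- PLY ----

#' Write a mesh as PLY
#'
#' @param mesh `trimesh`.
#' @param path output file path.
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#'   Binary stores coordinates as float32.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    "comment produced by elbowaxis",
    paste("element vertex", nv),
    "property float x", "property float y", "property float z",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "ascii") {
    vtxt <- apply(mesh$vertices, 1L, function(r) {
      paste(format(r, digits = 9, trim = TRUE, scientific = FALSE),
            collapse = " ")
    })
    writeLines(vtxt, con)
    ftxt <- apply(mesh$faces - 1L, 1L, function(r) paste(c(3L, r), collapse = " "))
    writeLines(ftxt, con)
  } else {
    writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "little")
    fm <- t(mesh$faces - 1L)
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fm[, i]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Supports the layouts written by [write_ply()]: ascii or binary
#' little-endian, float32 vertex x/y/z, uchar-counted int face lists.
#'
#' @param path PLY file.
#' @return `trimesh`.
#' @export
read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  read_line <- function() {
    chars <- character(0L)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "\n") break
      if (ch != "\r") chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
  }
  if (read_line() != "ply") stop("not a PLY file: ", path, call. = FALSE)
  fmt <- NULL; nv <- NULL; nf <- NULL; in_vertex <- FALSE
  vertex_props <- character(0L)
  repeat {
    ln <- read_line()
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element" && tok[2L] == "vertex") {
      nv <- as.integer(tok[3L]); in_vertex <- TRUE
    } else if (tok[1L] == "element" && tok[2L] == "face") {
      nf <- as.integer(tok[3L]); in_vertex <- FALSE
    } else if (tok[1L] == "property" && in_vertex) {
      vertex_props <- c(vertex_props, tok[length(tok)])
    } else if (tok[1L] == "end_header") break
  }
  if (!identical(vertex_props, c("x", "y", "z"))) {
    stop("unsupported PLY vertex layout: ", paste(vertex_props, collapse = ","),
         call. = FALSE)
  }
  if (fmt == "ascii") {
    txt <- readLines(con)
    vtx <- do.call(rbind, lapply(strsplit(trimws(txt[seq_len(nv)]), "\\s+"),
                                 as.numeric))
    fl <- lapply(strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+"), as.integer)
    if (any(vapply(fl, `[`, integer(1L), 1L) != 3L)) {
      stop("non-triangular PLY face encountered", call. = FALSE)
    }
    faces <- do.call(rbind, lapply(fl, function(x) x[2:4])) + 1L
  } else if (fmt == "binary_little_endian") {
    vtx <- matrix(readBin(con, "double", n = 3L * nv, size = 4L,
                          endian = "little"), ncol = 3L, byrow = TRUE)
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      idx <- readBin(con, "integer", n = cnt, size = 4L, endian = "little")
      if (cnt != 3L) stop("non-triangular PLY face encountered", call. = FALSE)
      faces[i, ] <- idx + 1L
    }
  } else {
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  }
  trimesh(vtx, faces)
}

## ---- STL (binary) ----

#' Write a mesh as binary STL
#'
#' @param mesh `trimesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "elbowaxis binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  a <- v[f[, 1L], , drop = FALSE]
  ab <- v[f[, 2L], , drop = FALSE] - a
  ac <- v[f[, 3L], , drop = FALSE] - a
  nrm <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
               ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
               ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  for (i in seq_len(nrow(f))) {
    rec <- rbind(nrm[i, ], v[f[i, ], , drop = FALSE])
    writeBin(as.vector(t(rec)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}

#' Read a binary STL mesh
#'
#' Coincident corner vertices are merged so downstream topology
#' (watertightness, sectioning) works.
#'
#' @param path STL file.
#' @return `trimesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", size = 4L, endian = "little")
  rec <- matrix(0, nf, 9L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    rec[i, ] <- vals[4:12]
  }
  vtx <- matrix(as.vector(t(rec)), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  merge_duplicate_vertices(vtx, faces)
}
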
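# Triangle-mesh container and plain-text mesh I/O (ASCII STL / PLY / OBJ).
# Vertices are in mm. Validation drops zero-area faces so downstream
# normal computations are well defined.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix, mm
#' @param faces m x 3 integer matrix of 1-based vertex indices
#' @param validate drop zero-area faces and check index ranges
#' @return object of class `tri_mesh`
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  V <- as_point_matrix(vertices)
  F_ <- as.matrix(faces)
  storage.mode(F_) <- "integer"
  if (ncol(F_) != 3) stop("faces must be m x 3")
  if (validate) {
    if (nrow(F_) > 0 && (min(F_) < 1 || max(F_) > nrow(V)))
      stop("face indices out of range")
    if (nrow(F_) > 0) {
      a <- V[F_[, 2], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
      b <- V[F_[, 3], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
      n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
      area2 <- sqrt(rowSums(n^2))
      F_ <- F_[area2 > 1e-12, , drop = FALSE]
    }
  }
  structure(list(vertices = V, faces = F_), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Per-face normals and areas
#' @param mesh a [tri_mesh()]
#' @return list with `normals` (m x 3, unit) and `areas` (mm^2)
#' @export
mesh_face_normals <- function(mesh) {
  V <- mesh$vertices; F_ <- mesh$faces
  a <- V[F_[, 2], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  b <- V[F_[, 3], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  list(normals = n / len, areas = len / 2)
}

#' Area-weighted per-vertex unit normals
#' @param mesh a [tri_mesh()]
#' @return n x 3 matrix of unit normals (zero rows for unreferenced vertices)
#' @export
mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh)
  w <- fn$normals * fn$areas      # area-weighted face normals
  N <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (j in 1:3) N[, j] <- N[, j] + unname(tapply_sum(w[, j], idx, nrow(N)))
  }
  len <- sqrt(rowSums(N^2))
  len[len < 1e-12] <- 1
  N / len
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Rigidly transform a mesh
#' @param mesh a [tri_mesh()]
#' @param tr a [rigid_transform()]
#' @return transformed mesh
#' @export
transform_mesh <- function(mesh, tr) {
  tri_mesh(rt_apply(tr, mesh$vertices), mesh$faces, validate = FALSE)
}

## ---- I/O --------------------------------------------------------------

#' Read a mesh file (STL, PLY or OBJ; format chosen by extension)
#'
#' Coordinates are taken to be in mm. ASCII and binary STL are both
#' accepted; PLY and OBJ readers accept the ASCII dialects.
#'
#' @param path file path ending in .stl, .ply or .obj
#' @return a [tri_mesh()]
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a mesh file (ASCII STL, PLY or OBJ by extension)
#' @param mesh a [tri_mesh()]
#' @param path output path
#' @param scalars optional per-vertex numeric scalar (PLY only), written as
#'   a `quality` property — used for deviation-map export
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, scalars = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl_ascii(mesh, path),
         ply = write_ply_ascii(mesh, path, scalars),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 80)
  if (grepl("^\\s*solid", rawToChar(head[1:40]), useBytes = TRUE) &&
      is_ascii_stl(path)) read_stl_ascii(path) else read_stl_binary(path)
}

is_ascii_stl <- function(path) {
  # binary STL can also start with "solid"; check for a facet keyword
  txt <- suppressWarnings(readLines(path, n = 5L, warn = FALSE))
  any(grepl("facet|endsolid", txt, useBytes = TRUE))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed STL file (vertex count not a multiple of 3): ", path)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x) {
    v <- suppressWarnings(as.numeric(x[2:4]))
    if (any(is.na(v))) stop("malformed STL vertex line in ", path)
    v
  }, numeric(3)))
  stl_soup_to_mesh(nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!length(nf) || nf <= 0 || nf > 5e7) stop("malformed binary STL: ", path)
  rec <- readBin(con, "raw", n = nf * 50)
  if (length(rec) < nf * 50) stop("truncated binary STL: ", path)
  m <- matrix(rec, ncol = 50, byrow = TRUE)
  vals <- t(apply(m[, 13:48, drop = FALSE], 1, function(r)
    readBin(r, "numeric", n = 9, size = 4, endian = "little")))
  soup <- matrix(t(matrix(t(vals), nrow = 3)), ncol = 3, byrow = TRUE)
  stl_soup_to_mesh(soup)
}

# STL stores a triangle soup with duplicated vertices; merge identical
# coordinates (to 1e-6 mm) to recover shared topology.
stl_soup_to_mesh <- function(soup) {
  key <- apply(round(soup, 6), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  tri_mesh(soup[uk, , drop = FALSE],
           matrix(idx, ncol = 3, byrow = TRUE))
}

write_stl_ascii <- function(mesh, path) {
  fn <- mesh_face_normals(mesh)$normals
  V <- mesh$vertices; F_ <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid orthomotion", con)
  for (i in seq_len(nrow(F_))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      v <- V[F_[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid orthomotion", con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("malformed PLY file: ", path)
  if (!any(grepl("format ascii", lines[1:10])))
    stop("only ASCII PLY is supported: ", path)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("malformed PLY header: ", path)
  header <- trimws(lines[1:hend])
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", header, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("malformed PLY header: ", path)
  body <- lines[(hend + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vrows <- strsplit(trimws(body[1:nv]), "\\s+")
  V <- t(vapply(vrows, function(x) as.numeric(x[1:3]), numeric(3)))
  frows <- strsplit(trimws(body[(nv + 1):(nv + nf)]), "\\s+")
  F_ <- t(vapply(frows, function(x) {
    n <- as.integer(x[1])
    if (n != 3) stop("only triangle faces supported in PLY: ", path)
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  if (any(is.na(V)) || any(is.na(F_))) stop("malformed PLY body: ", path)
  tri_mesh(V, F_)
}

write_ply_ascii <- function(mesh, path, scalars = NULL) {
  V <- mesh$vertices; F_ <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z")
  if (!is.null(scalars)) {
    stopifnot(length(scalars) == nrow(V))
    hdr <- c(hdr, "property float quality")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(F_)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(scalars)) {
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], scalars), con)
  }
  writeLines(sprintf("3 %d %d %d", F_[, 1] - 1L, F_[, 2] - 1L, F_[, 3] - 1L), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("malformed OBJ file: ", path)
  V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  F_ <- t(vapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ix <- as.integer(sub("/.*$", "", x[2:4]))
    if (any(is.na(ix))) stop("malformed OBJ face in ", path)
    ix
  }, integer(3)))
  if (any(is.na(V))) stop("malformed OBJ vertex in ", path)
  tri_mesh(V, F_)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  V <- mesh$vertices; F_ <- mesh$faces
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", F_[, 1], F_[, 2], F_[, 3]), con)
}
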
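#' Triangle mesh objects
#'
#' A `talus_mesh` is a minimal triangle-mesh container: an `n x 3` numeric
#' matrix of vertex coordinates (millimetres) and an `m x 3` integer matrix
#' of 1-based vertex indices, one row per triangular face. On construction,
#' exactly coincident vertices are merged and degenerate (zero-area or
#' repeated-index) faces are dropped.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param clean merge duplicate vertices and drop degenerate faces?
#' @return An object of class `talus_mesh` with elements `vertices` and
#'   `faces`.
#' @export
mesh <- function(vertices, faces, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns", call. = FALSE)
  if (nrow(faces) == 0L) stop("mesh has no faces", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be triangles (3 columns)", call. = FALSE)
  if (anyNA(vertices) || anyNA(faces)) stop("mesh contains missing values", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range", call. = FALSE)
  }
  out <- structure(list(vertices = vertices, faces = faces), class = "talus_mesh")
  if (clean) out <- clean_mesh(out)
  out
}

# Merge exactly-coincident vertices and drop degenerate faces.
clean_mesh <- function(m) {
  key <- paste(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3], sep = "/")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  verts <- m$vertices[first, , drop = FALSE]
  faces <- matrix(remap[m$faces], ncol = 3L)
  a <- faces[, 1]; b <- faces[, 2]; c <- faces[, 3]
  nondegen <- a != b & b != c & a != c
  # zero-area faces (distinct indices but collinear vertices)
  if (any(nondegen)) {
    idx <- which(nondegen)
    e1 <- verts[b[idx], , drop = FALSE] - verts[a[idx], , drop = FALSE]
    e2 <- verts[c[idx], , drop = FALSE] - verts[a[idx], , drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    area2 <- sqrt(cx^2 + cy^2 + cz^2)
    nondegen[idx[area2 <= 1e-14]] <- FALSE
  }
  faces <- faces[nondegen, , drop = FALSE]
  if (nrow(faces) == 0L) stop("mesh has no non-degenerate faces", call. = FALSE)
  structure(list(vertices = verts, faces = faces), class = "talus_mesh")
}

#' @export
print.talus_mesh <- function(x, ...) {
  cat("<talus_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' Reads the ASCII variants of the three common surface-mesh formats.
#' Duplicate vertices are merged and degenerate faces dropped at load time;
#' the raw and cleaned counts are recorded as attributes.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"stl"`; guessed from the file
#'   extension when missing.
#' @param scale multiply all coordinates by this factor at load (use to
#'   convert meshes not stored in millimetres).
#' @return A [mesh()] object.
#' @export
read_mesh <- function(path, format = NULL, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(format, c("ply", "obj", "stl"))
  raw <- switch(format,
    ply = read_ply_ascii(path),
    obj = read_obj(path),
    stl = read_stl_ascii(path)
  )
  n_raw <- nrow(raw$vertices)
  out <- mesh(raw$vertices * scale, raw$faces)
  attr(out, "n_raw_vertices") <- n_raw
  attr(out, "source") <- path
  out
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("not a PLY file (no end_header): ", path, call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  if (!identical(header[1], "ply")) stop("not a PLY file: ", path, call. = FALSE)
  fmt <- grep("^format", header, value = TRUE)
  if (length(fmt) && !grepl("ascii", fmt[1])) {
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path, call. = FALSE)
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vlines <- body[seq_len(nv)]
  flines <- body[nv + seq_len(nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("non-triangular face in PLY", call. = FALSE)
    as.integer(x[2:4]) + 1L  # PLY is 0-based
  }))
  list(vertices = verts, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("no vertices/faces in OBJ: ", path, call. = FALSE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ids <- vapply(x[-1], function(tok) as.integer(strsplit(tok, "/")[[1]][1]), integer(1))
    if (length(ids) != 3L) stop("non-triangular face in OBJ", call. = FALSE)
    ids
  }))
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L) {
    stop("not a valid ASCII STL (vertex count not a multiple of 3): ", path, call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Write a mesh as ASCII PLY
#'
#' @param m a [mesh()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path) {
  stopifnot(inherits(m, "talus_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(m$vertices)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(m$faces)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(apply(format(m$vertices, digits = 17, scientific = FALSE, trim = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3L, m$faces[, 1] - 1L, m$faces[, 2] - 1L, m$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read and write region sidecar files
#'
#' Mesh formats carry no standard region labels, so anatomical regions
#' (e.g. `"LTF"`, the lateral tibial facet, and `"FFG"`, the flexor
#' fibularis groove) travel as a JSON sidecar mapping label to a list of
#' 1-based vertex indices.
#'
#' @param path JSON file path.
#' @return A named list of integer vectors.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region sidecar not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, as.integer)
}

#' @param regions named list of integer vertex-id vectors.
#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  stopifnot(is.list(regions), !is.null(names(regions)))
  jsonlite::write_json(lapply(regions, as.integer), path)
  invisible(path)
}
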
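# STL (ASCII and binary) and PLY (ASCII) surface-mesh I/O. Mesh files carry no
# coordinate-frame metadata, so the anatomical frame is always supplied by the
# caller.

#' Read a surface mesh from STL or PLY
#'
#' Reads a triangulated surface from an STL file (binary or ASCII, detected
#' from the content) or an ASCII PLY file, deduplicates vertices to rebuild
#' topology, and attaches the declared anatomical frame.
#'
#' @param path Path to an `.stl` or `.ply` file.
#' @param frame An [anatomical_frame()]; never guessed from the file.
#' @return A [fem_mesh()].
#' @export
read_mesh <- function(path, frame) {
  if (!file.exists(path)) {
    abort(sprintf("mesh file not found: %s", path), class = "femtor_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  vf <- switch(ext,
    stl = read_stl_raw(path),
    ply = read_ply_raw(path),
    abort(sprintf("unsupported mesh format '.%s' (need .stl or .ply)", ext),
          class = "femtor_error_format"))
  if (nrow(vf$vertices) == 0L || nrow(vf$faces) == 0L) {
    abort(sprintf("empty mesh in %s", path), class = "femtor_error_empty")
  }
  fem_mesh(vf$vertices, vf$faces, frame)
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh A [fem_mesh()].
#' @param path Output path; format chosen from the extension (`.stl` or
#'   `.ply`).
#' @param binary For STL, write the binary flavour (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "fem_mesh"))
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch(suppressWarnings({
    switch(ext,
      stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
      ply = write_ply_ascii(mesh, path),
      abort(sprintf("unsupported mesh format '.%s' (need .stl or .ply)", ext),
            class = "femtor_error_format"))
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) {
    if (inherits(ok, "femtor_error_format")) stop(ok)
    abort(sprintf("failed to write %s: %s", path, conditionMessage(ok)),
          class = "femtor_error_io")
  }
  invisible(path)
}

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  # binary STL has exactly 84 + 50*ntri bytes; ASCII starts with "solid"
  if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri)) return(TRUE)
  !identical(rawToChar(header[1:5]), "solid")
}

read_stl_raw <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (is.na(ntri) || ntri <= 0) {
      abort(sprintf("corrupt binary STL: %s", path), class = "femtor_error_format")
    }
    rec <- readBin(con, "raw", 50 * ntri)
    if (length(rec) < 50 * ntri) {
      abort(sprintf("truncated binary STL: %s", path), class = "femtor_error_format")
    }
    rec <- matrix(rec, nrow = 50)
    coords <- readBin(as.vector(rec[13:48, ]), "numeric", size = 4, n = 9 * ntri,
                      endian = "little")
    v <- matrix(coords, ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      abort(sprintf("corrupt ASCII STL: %s", path), class = "femtor_error_format")
    }
    parts <- strsplit(trimws(vl), "\\s+")
    v <- do.call(rbind, lapply(parts, function(p) as.numeric(p[2:4])))
    if (anyNA(v)) {
      abort(sprintf("corrupt ASCII STL: %s", path), class = "femtor_error_format")
    }
  }
  list(vertices = v, faces = matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE))
}

facet_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-30] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  f <- mesh$faces
  n <- facet_normals(mesh)
  tri <- cbind(n,
               mesh$vertices[f[, 1], , drop = FALSE],
               mesh$vertices[f[, 2], , drop = FALSE],
               mesh$vertices[f[, 3], , drop = FALSE])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  payload <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
  payload <- matrix(payload, nrow = 48)
  rec <- rbind(payload, matrix(as.raw(0L), nrow = 2, ncol = ncol(payload)))
  writeBin(as.vector(rec), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  f <- mesh$faces
  n <- facet_normals(mesh)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("solid femtor", con)
  v1 <- mesh$vertices[f[, 1], , drop = FALSE]
  v2 <- mesh$vertices[f[, 2], , drop = FALSE]
  v3 <- mesh$vertices[f[, 3], , drop = FALSE]
  lines <- sprintf(
    "facet normal %.12g %.12g %.12g\nouter loop\nvertex %.12g %.12g %.12g\nvertex %.12g %.12g %.12g\nvertex %.12g %.12g %.12g\nendloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    v1[, 1], v1[, 2], v1[, 3],
    v2[, 1], v2[, 2], v2[, 3],
    v3[, 1], v3[, 2], v3[, 3])
  writeLines(lines, con)
  writeLines("endsolid femtor", con)
  invisible(path)
}

read_ply_raw <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || trimws(txt[1]) != "ply") {
    abort(sprintf("not a PLY file: %s", path), class = "femtor_error_format")
  }
  end <- match("end_header", trimws(txt))
  if (is.na(end)) {
    abort(sprintf("corrupt PLY header: %s", path), class = "femtor_error_format")
  }
  header <- trimws(txt[seq_len(end)])
  if (!any(grepl("^format ascii", header))) {
    abort(sprintf("only ASCII PLY is supported: %s", path), class = "femtor_error_format")
  }
  ev <- grep("^element vertex ", header, value = TRUE)
  ef <- grep("^element face ", header, value = TRUE)
  if (length(ev) != 1L || length(ef) != 1L) {
    abort(sprintf("corrupt PLY header: %s", path), class = "femtor_error_format")
  }
  nv <- as.integer(sub("^element vertex ", "", ev))
  nf <- as.integer(sub("^element face ", "", ef))
  body <- txt[(end + 1):length(txt)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) {
    abort(sprintf("truncated PLY body: %s", path), class = "femtor_error_format")
  }
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) {
    p <- as.integer(p)
    if (is.na(p[1]) || p[1] != 3L) {
      abort("only triangulated PLY faces are supported", class = "femtor_error_format")
    }
    p[2:4] + 1L
  }))
  if (anyNA(v) || anyNA(faces)) {
    abort(sprintf("corrupt PLY body: %s", path), class = "femtor_error_format")
  }
  list(vertices = v, faces = faces)
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment femtor surface mesh",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  f0 <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  invisible(path)
}
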
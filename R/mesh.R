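#' Anatomical coordinate frame declaration
#'
#' All geometry in femtor is interpreted in an LPS patient frame: x points to
#' the patient's left, y posterior, z superior (the DICOM patient frame of a
#' supine scan). The frame tag also carries the side of the femur, which is
#' required for the sign convention of the torsion angle (antetorsion
#' positive on both sides).
#'
#' @param side `"left"` or `"right"`.
#' @param convention Frame convention label; only `"LPS"` is supported and any
#'   other value is rejected.
#' @return An object of class `fem_frame`.
#' @export
#' @examples
#' anatomical_frame("right")
anatomical_frame <- function(side, convention = "LPS") {
  if (!identical(convention, "LPS")) {
    abort(sprintf("unsupported frame convention '%s' (only 'LPS' is supported)", convention),
          class = "femtor_error_frame")
  }
  side <- match.arg(side, c("left", "right"))
  structure(list(convention = "LPS", side = side), class = "fem_frame")
}

#' @export
print.fem_frame <- function(x, ...) {
  cat(sprintf("<frame> %s, %s femur\n", x$convention, x$side))
  invisible(x)
}

#' Triangulated surface mesh
#'
#' Constructs a triangle mesh from vertex coordinates (mm) and 1-based face
#' indices, after deduplicating vertices (STL files store triangle soup) and
#' dropping degenerate (zero-area) faces. The anatomical frame must be
#' declared by the caller; it is never guessed from the file.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param frame A [anatomical_frame()] object.
#' @param dedup_tol Vertex deduplication tolerance in mm.
#' @return An object of class `fem_mesh` with fields `vertices`, `faces`,
#'   `frame`.
#' @export
#' @examples
#' m <- mesh_cube(frame = anatomical_frame("right"))
#' m
fem_mesh <- function(vertices, faces, frame, dedup_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (!inherits(frame, "fem_frame")) {
    abort("`frame` must be an anatomical_frame()", class = "femtor_error_frame")
  }
  if (nrow(vertices) == 0L || nrow(faces) == 0L) {
    abort("empty mesh: no vertices or no faces", class = "femtor_error_empty")
  }
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    abort("vertices must be n x 3 and faces m x 3", class = "femtor_error_format")
  }
  if (anyNA(vertices) || !all(is.finite(vertices))) {
    abort("vertex coordinates must be finite", class = "femtor_error_format")
  }
  if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices)) {
    abort("face indices out of range", class = "femtor_error_format")
  }
  # dedup vertices on a quantized key
  key <- apply(round(vertices / dedup_tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3L)
  # drop degenerate faces (repeated vertex or ~zero area)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  if (nrow(faces) > 0L) {
    a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-12, , drop = FALSE]
  }
  if (nrow(faces) == 0L) {
    abort("mesh has no non-degenerate faces", class = "femtor_error_empty")
  }
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<mesh> %d vertices, %d faces, %s %s femur\n",
              nrow(x$vertices), nrow(x$faces), x$frame$convention, x$frame$side))
  cat(sprintf("  bbox x [%.1f, %.1f] y [%.1f, %.1f] z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Mesh diagnostics
#'
#' Computes diagnostics for a triangle mesh: whether it is watertight (every
#' edge shared by exactly two faces with opposite orientation), the number of
#' connected components, the bounding box, and the count of degenerate faces
#' remaining (always 0 after construction). Diagnostics never raise; the
#' watertightness flag is computed, not asserted.
#'
#' @param mesh A [fem_mesh()].
#' @return A one-row tibble with columns `watertight`, `n_components`,
#'   `n_vertices`, `n_faces`, `n_degenerate`, `n_boundary_edges`, and bounding
#'   box columns `x_min` ... `z_max` (mm).
#' @export
#' @examples
#' validate_mesh(mesh_icosphere(radius = 10, frame = anatomical_frame("left")))
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "fem_mesh"))
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])   # directed half-edges
  ekey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(ekey)
  # opposite orientation: each undirected edge must appear once in each direction
  dkey <- paste(he[, 1], he[, 2])
  watertight <- all(cnt == 2L) && !anyDuplicated(dkey)
  n_boundary <- sum(cnt == 1L)
  g <- igraph::graph_from_edgelist(unique(he), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$no
  a <- mesh$vertices[f[, 2], , drop = FALSE] - mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 3], , drop = FALSE] - mesh$vertices[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n_degen <- sum(sqrt(rowSums(cr^2)) <= 1e-12)
  bb <- apply(mesh$vertices, 2, range)
  tibble::tibble(
    watertight = watertight, n_components = comp,
    n_vertices = nrow(mesh$vertices), n_faces = nrow(f),
    n_degenerate = n_degen, n_boundary_edges = n_boundary,
    x_min = bb[1, 1], x_max = bb[2, 1],
    y_min = bb[1, 2], y_max = bb[2, 2],
    z_min = bb[1, 3], z_max = bb[2, 3])
}

#' Affine transforms of a mesh
#'
#' `transform_mesh()` applies `v -> v %*% t(A) + b` to every vertex; when A has
#' negative determinant (a reflection) the face winding is reversed so normals
#' keep pointing outward. `mirror_mesh()` mirrors across the sagittal plane
#' (x = const in LPS) and flips the side flag, turning a right femur model into
#' a left one.
#'
#' @param mesh A [fem_mesh()].
#' @param A 3 x 3 linear part.
#' @param b Length-3 translation (mm).
#' @param x0 Sagittal plane offset for mirroring (mm).
#' @return A transformed `fem_mesh`.
#' @export
transform_mesh <- function(mesh, A = diag(3), b = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "fem_mesh"))
  v <- mesh$vertices %*% t(A)
  v <- sweep(v, 2, vec3(b), "+")
  f <- mesh$faces
  if (det(A) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  out <- mesh
  out$vertices <- v
  out$faces <- f
  out
}

#' @rdname transform_mesh
#' @export
mirror_mesh <- function(mesh, x0 = 0) {
  out <- transform_mesh(mesh, A = diag(c(-1, 1, 1)), b = c(2 * x0, 0, 0))
  out$frame$side <- if (mesh$frame$side == "left") "right" else "left"
  out
}
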
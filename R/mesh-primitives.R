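# Analytic test solids. These exist for validation: closed-form areas and
# centroids make them oracles for the cross-section and sphere-fit code.

#' Analytic test meshes
#'
#' `mesh_cube()` builds an axis-aligned box, `mesh_cylinder()` a closed
#' cylinder along z, `mesh_icosphere()` a subdivided icosahedron, and
#' `mesh_revolution()` a closed surface of revolution about the z axis with
#' radius profile `radius_fun(z)` (e.g. a hyperboloid waist).
#'
#' @param lo,hi Cube corners (mm).
#' @param radius,height Cylinder radius and height (mm); the cylinder spans
#'   `z` in `[0, height]`.
#' @param n_seg Segments around the circumference.
#' @param n_z Rings along z.
#' @param subdivisions Icosphere subdivision level (0 = icosahedron).
#' @param radius_fun Function of z returning the profile radius (mm), > 0.
#' @param z_range Length-2 numeric, axial extent of the revolution solid.
#' @param center Sphere center (mm).
#' @param frame An [anatomical_frame()].
#' @return A [fem_mesh()].
#' @name test_meshes
NULL

#' @rdname test_meshes
#' @export
mesh_cube <- function(lo = c(0, 0, 0), hi = c(1, 1, 1),
                      frame = anatomical_frame("right")) {
  lo <- vec3(lo); hi <- vec3(hi)
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # 12 triangles, outward winding (vertex order of expand.grid: x fastest)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = hi (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = lo (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = hi (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = lo (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = hi (+x)
  fem_mesh(v, f, frame)
}

# closed tube around z from stacked rings; used by cylinder and revolution
tube_mesh <- function(zs, radii, n_seg, frame) {
  stopifnot(length(zs) == length(radii), length(zs) >= 2L)
  ang <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  rings <- lapply(seq_along(zs), function(i) {
    cbind(radii[i] * cos(ang), radii[i] * sin(ang), zs[i])
  })
  v <- do.call(rbind, rings)
  nz <- length(zs)
  f <- list()
  for (i in seq_len(nz - 1L)) {
    a <- (i - 1L) * n_seg + seq_len(n_seg)
    b <- a + n_seg
    a2 <- c(a[-1], a[1])
    b2 <- c(b[-1], b[1])
    f[[i]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  # cap fans (apex on axis)
  v <- rbind(v, c(0, 0, zs[1]), c(0, 0, zs[nz]))
  bot <- nrow(v) - 1L
  top <- nrow(v)
  a <- seq_len(n_seg)
  a2 <- c(a[-1], a[1])
  t1 <- (nz - 1L) * n_seg + a
  t2 <- (nz - 1L) * n_seg + a2
  f[[length(f) + 1L]] <- rbind(cbind(bot, a2, a), cbind(top, t1, t2))
  fem_mesh(v, do.call(rbind, f), frame)
}

#' @rdname test_meshes
#' @export
mesh_cylinder <- function(radius = 10, height = 40, n_seg = 64L, n_z = 8L,
                          frame = anatomical_frame("right")) {
  zs <- seq(0, height, length.out = n_z + 1L)
  tube_mesh(zs, rep(radius, n_z + 1L), n_seg, frame)
}

#' @rdname test_meshes
#' @export
mesh_revolution <- function(radius_fun, z_range = c(-20, 20), n_seg = 96L,
                            n_z = 60L, frame = anatomical_frame("right")) {
  zs <- seq(z_range[1], z_range[2], length.out = n_z + 1L)
  radii <- vapply(zs, radius_fun, numeric(1))
  stopifnot(all(radii > 0))
  tube_mesh(zs, radii, n_seg, frame)
}

#' @rdname test_meshes
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3L,
                           frame = anatomical_frame("right")) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(ekey)
    mid_idx <- nrow(v) + match(ekey, uk)
    ue <- edges[!duplicated(ekey), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    m12 <- mid_idx[seq_len(nf)]
    m23 <- mid_idx[nf + seq_len(nf)]
    m31 <- mid_idx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, vec3(center), "+")
  fem_mesh(v, f, frame)
}
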
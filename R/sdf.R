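# Signed-distance-field construction kit for the synthetic femur. Fields are
# evaluated on n x 3 point matrices and are negative inside the solid. The
# isosurface is extracted with marching tetrahedra (src/marching_tets.cpp),
# which yields a watertight, consistently oriented triangulation.

sdf_sphere <- function(P, center, radius) {
  sqrt(rowSums(sweep(P, 2, center)^2)) - radius
}

# capsule: cylinder of radius r around segment a-b with spherical caps
sdf_capsule <- function(P, a, b, radius) {
  ab <- b - a
  len2 <- sum(ab^2)
  Pa <- sweep(P, 2, a)
  t <- pmin(pmax(as.numeric(Pa %*% ab) / len2, 0), 1)
  closest <- outer(t, ab)
  sqrt(rowSums((Pa - closest)^2)) - radius
}

# ellipsoid, scaled-space approximation (exact zero level set)
sdf_ellipsoid <- function(P, center, semi) {
  Q <- sweep(sweep(P, 2, center), 2, semi, "/")
  k0 <- sqrt(rowSums(Q^2))
  Q2 <- sweep(Q, 2, semi, "/")
  k1 <- sqrt(rowSums(Q2^2))
  ifelse(k1 > 1e-12, k0 * (k0 - 1) / k1, -min(semi))
}

# half-space keeping the region where `P %*% normal >= offset`
sdf_halfspace <- function(P, normal, offset) {
  offset - as.numeric(P %*% normal)
}

# quadratic polynomial smooth minimum with blending radius k (mm)
smin <- function(a, b, k = 3) {
  h <- pmax(k - abs(a - b), 0) / k
  pmin(a, b) - h * h * k * 0.25
}

# hard intersection (used to cut scan segments out of the full femur)
sdf_intersect <- function(a, b) pmax(a, b)

# Extract the zero isosurface of `field_fun` on a regular grid.
sdf_mesh <- function(field_fun, x_range, y_range, z_range, pitch, frame) {
  xs <- seq(x_range[1], x_range[2], by = pitch)
  ys <- seq(y_range[1], y_range[2], by = pitch)
  zs <- seq(z_range[1], z_range[2], by = pitch)
  G <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  f <- field_fun(G)
  if (!any(f < 0)) {
    abort("isosurface extraction failed: field has no interior on the grid",
          class = "femtor_error_parameter")
  }
  res <- .marching_tets(as.numeric(f), xs, ys, zs)
  fem_mesh(res$vertices, res$faces, frame)
}
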
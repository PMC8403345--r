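# Low-level 3D primitives shared by the torsion pipeline. Points are length-3
# numeric vectors in mm; point sets are n x 3 matrices.

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || !all(is.finite(x))) {
    abort("expected a finite 3D point/vector", class = "femtor_error_geometry")
  }
  x
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) {
    abort(paste0("cannot normalize a zero-length ", what),
          class = "femtor_error_degenerate")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Oriented plane in 3D
#'
#' A plane is stored as a point on the plane plus a unit normal. Used for
#' neck cross-sections, axial shaft sections and the posterior condylar plane.
#'
#' @param point Numeric length-3, a point on the plane (mm).
#' @param normal Numeric length-3, plane normal; normalized internally.
#' @return An object of class `fem_plane` with fields `point` and `normal`
#'   (unit length within 1e-9).
#' @export
#' @examples
#' plane3(c(0, 0, 5), c(0, 0, 2))
plane3 <- function(point, normal) {
  structure(list(point = vec3(point), normal = unitize(vec3(normal), "plane normal")),
            class = "fem_plane")
}

#' Oriented axis (line) in 3D
#'
#' @param point Numeric length-3, a point on the axis (mm).
#' @param direction Numeric length-3, axis direction; normalized internally.
#' @return An object of class `fem_axis` with fields `point` and `direction`
#'   (unit length within 1e-9).
#' @export
#' @examples
#' axis3(c(0, 0, 0), c(0, 0, 1))
axis3 <- function(point, direction) {
  structure(list(point = vec3(point), direction = unitize(vec3(direction), "axis direction")),
            class = "fem_axis")
}

#' @export
print.fem_plane <- function(x, ...) {
  cat(sprintf("<plane> point (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' @export
print.fem_axis <- function(x, ...) {
  cat(sprintf("<axis> point (%.3f, %.3f, %.3f) mm, direction (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# Rotation matrix for angle `theta` (radians) about unit axis `k` (Rodrigues).
rotation_about <- function(k, theta) {
  k <- unitize(vec3(k), "rotation axis")
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a set of 3D points: an algebraic (linear least squares)
#' fit provides the starting values, followed by geometric Gauss-Newton
#' refinement of the sum of squared radial residuals. Used to locate the
#' femoral head center from a surface patch selected on the head.
#'
#' @param points An n x 3 numeric matrix (n >= 4) of points (mm), not all
#'   coplanar.
#' @param max_iter,tol Gauss-Newton iteration cap and convergence tolerance on
#'   the parameter update (mm).
#' @return An object of class `fem_sphere`: `center` (mm), `radius` (mm) and
#'   `rms_residual` (mm, root mean squared radial residual).
#' @export
#' @examples
#' u <- matrix(rnorm(300), ncol = 3)
#' u <- u / sqrt(rowSums(u^2))
#' fit_sphere(sweep(24 * u, 2, c(10, -5, 3), "+"))
fit_sphere <- function(points, max_iter = 50L, tol = 1e-12) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 4L || anyNA(points)) {
    abort("sphere fit needs an n x 3 matrix of at least 4 finite points",
          class = "femtor_error_degenerate")
  }
  # coplanarity / degeneracy check via the centered covariance spectrum
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    abort("sphere fit is degenerate: points are (nearly) coplanar",
          class = "femtor_error_degenerate")
  }
  # algebraic fit: |p|^2 = 2 c.p + (r^2 - |c|^2)
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  beta <- qr.solve(A, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  radius <- sqrt(max(r2, .Machine$double.eps))
  # geometric refinement: minimize sum (|p - c| - r)^2 over (c, r)
  for (it in seq_len(max_iter)) {
    D <- sweep(points, 2, center)
    d <- sqrt(rowSums(D^2))
    if (any(d < 1e-12)) break
    r_hat <- mean(d)
    J <- cbind(-D / d, -1)           # d residual / d (c, r)
    res <- d - r_hat
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    center <- center + step[1:3]
    radius <- r_hat + step[4]
    if (vnorm(step) < tol) break
  }
  D <- sweep(points, 2, center)
  d <- sqrt(rowSums(D^2))
  radius <- mean(d)
  structure(list(center = as.numeric(center), radius = radius,
                 rms_residual = sqrt(mean((d - radius)^2))),
            class = "fem_sphere")
}

#' @export
print.fem_sphere <- function(x, ...) {
  cat(sprintf("<sphere> center (%.3f, %.3f, %.3f) mm, radius %.3f mm, rms residual %.4f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}
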
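# Shared fixtures and independent oracles. Synthetic femurs are expensive to
# extract, so they are generated lazily and cached for the whole test run.

.femur_cache <- new.env(parent = emptyenv())

cached_femur <- function(theta = 15, side = "right", noise_sd = 0,
                         pitch = 1.0, seed = 1L) {
  key <- sprintf("t%g_%s_n%g_p%g_s%d", theta, side, noise_sd, pitch, seed)
  if (is.null(.femur_cache[[key]])) {
    .femur_cache[[key]] <- generate_femur(
      femur_params(theta = theta, side = side, noise_sd = noise_sd,
                   pitch = pitch, seed = seed))
  }
  .femur_cache[[key]]
}

measure_femur <- function(fem) {
  params <- params_from_ground_truth(fem$truth, fem$proximal)
  measure_torsion(fem$proximal, fem$distal, params)
}

# --- independent ICC oracles -----------------------------------------------

# brute-force two-way ANOVA by explicit summation over cells
icc_bruteforce <- function(M) {
  n <- nrow(M)
  k <- ncol(M)
  grand <- sum(M) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(M[i, ]) / k - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(M[, j]) / n - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (M[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# mean squares via stats::aov on the long layout (independent route)
icc_aov <- function(M) {
  n <- nrow(M)
  k <- ncol(M)
  d <- data.frame(y = as.vector(M),
                  unit = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ unit + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# --- sphere-fit oracle ------------------------------------------------------

# grid search over candidate centers (radius profiled out as the mean
# distance), minimizing the sum of squared radial residuals
sphere_grid_oracle <- function(points, center0, half_width = 0.1, step = 0.01) {
  offs <- seq(-half_width, half_width, by = step)
  best <- NULL
  for (dx in offs) for (dy in offs) for (dz in offs) {
    ctr <- center0 + c(dx, dy, dz)
    d <- sqrt(rowSums(sweep(points, 2, ctr)^2))
    loss <- sum((d - mean(d))^2)
    if (is.null(best) || loss < best$loss) best <- list(center = ctr, loss = loss)
  }
  best$center
}

# --- SDF voxel oracle for cross-section centroids ---------------------------

# average of interior sample points of the generating field on the plane,
# restricted to a disc around `near` (the neck neighbourhood)
sdf_plane_centroid_oracle <- function(field, plane_point, plane_normal, near,
                                      radius, res = 0.25) {
  n <- plane_normal / sqrt(sum(plane_normal^2))
  e1 <- pracma::cross(n, if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma::cross(n, e1)
  g <- seq(-radius, radius, by = res)
  uv <- expand.grid(u = g, v = g)
  P <- outer(uv$u, e1) + outer(uv$v, e2)
  P <- sweep(P, 2, plane_point, "+")
  inside <- field(P) < 0
  keep <- inside & sqrt(rowSums(sweep(P, 2, near)^2)) <= radius
  colMeans(P[keep, , drop = FALSE])
}

expect_angle_close <- function(measured, true, tol) {
  expect_lt(abs(measured - true), tol)
}
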
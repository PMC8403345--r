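# Planar cross-sections of triangle meshes. The boundary is built from the
# exact triangle/plane intersection segments, chained into closed loops via
# shared mesh edges, which is robust because each mesh edge is crossed by the
# plane in exactly two incident triangles on a watertight mesh.

#' Planar cross-section of a mesh
#'
#' Intersects a triangle mesh with a plane and returns the boundary loops,
#' the enclosed area and the area centroid. Loops inherit the mesh
#' orientation: outer boundaries have positive signed area about the plane
#' normal and holes negative, so the reported area and centroid are those of
#' the enclosed region with holes subtracted.
#'
#' @param mesh A [fem_mesh()].
#' @param plane A [plane3()].
#' @return An object of class `fem_section`: `plane`, `loops` (list of k x 3
#'   matrices of ordered boundary points), `loop_areas` (signed, mm^2), `area`
#'   (mm^2, holes subtracted), `centroid` (mm, on the plane), and
#'   `largest_loop` (index of the largest-|area| loop, used for neck/shaft
#'   constructions).
#' @export
cross_section <- function(mesh, plane) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(plane, "fem_plane"))
  n <- plane$normal
  s <- as.numeric(mesh$vertices %*% n - sum(plane$point * n))
  s[s == 0] <- 1e-12                      # nudge on-plane vertices
  f <- mesh$faces
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  c12 <- s1 * s2 < 0
  c23 <- s2 * s3 < 0
  c31 <- s3 * s1 < 0
  hit <- which(c12 | c23 | c31)
  if (length(hit) == 0L) {
    abort("plane does not intersect the mesh", class = "femtor_error_empty_section")
  }
  # per crossing triangle: the two crossed edges, as (i, j) vertex pairs
  edge_point <- function(i, j) {
    ti <- s[i] / (s[i] - s[j])
    mesh$vertices[i, , drop = FALSE] * (1 - ti) +
      mesh$vertices[j, , drop = FALSE] * ti
  }
  seg_p <- vector("list", length(hit))
  seg_key <- matrix("", length(hit), 2)
  for (idx in seq_along(hit)) {
    fi <- hit[idx]
    vs <- f[fi, ]
    pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
    crossed <- c(c12[fi], c23[fi], c31[fi])
    pp <- pairs[crossed]
    pts <- matrix(0, 2, 3)
    keys <- character(2)
    for (k in 1:2) {
      i <- vs[pp[[k]][1]]; j <- vs[pp[[k]][2]]
      pts[k, ] <- edge_point(i, j)
      keys[k] <- paste0(min(i, j), "_", max(i, j))
    }
    seg_p[[idx]] <- pts
    seg_key[idx, ] <- keys
  }
  # preferred traversal direction per segment: n x facet normal (points along
  # the boundary so the solid lies left of it, i.e. loops CCW about +n);
  # unreliable for triangles nearly parallel to the plane, so it is only used
  # as a majority vote for whole-loop orientation below
  sub <- mesh
  sub$faces <- f[hit, , drop = FALSE]
  fn <- facet_normals(sub)
  # undirected chaining: on a watertight mesh every crossed mesh edge is
  # shared by exactly two crossing triangles
  keys <- unique(as.vector(seg_key))
  k1 <- match(seg_key[, 1], keys)
  k2 <- match(seg_key[, 2], keys)
  inc <- vector("list", length(keys))
  for (idx in seq_along(hit)) {
    inc[[k1[idx]]] <- c(inc[[k1[idx]]], idx)
    inc[[k2[idx]]] <- c(inc[[k2[idx]]], idx)
  }
  deg <- lengths(inc)
  if (any(deg != 2L)) {
    abort(sprintf("cross-section is not closed (%d unmatched boundary segments); mesh is not watertight at the cut",
                  sum(deg != 2L)),
          class = "femtor_error_open_section")
  }
  visited <- rep(FALSE, length(hit))
  loops <- list()
  for (start in seq_along(hit)) {
    if (visited[start]) next
    cur <- start
    at_key <- k1[start]          # enter `cur` at this key
    pts <- list()
    score <- 0
    repeat {
      visited[cur] <- TRUE
      exit_key <- if (at_key == k1[cur]) k2[cur] else k1[cur]
      p_in <- if (at_key == k1[cur]) seg_p[[cur]][1, ] else seg_p[[cur]][2, ]
      p_out <- if (at_key == k1[cur]) seg_p[[cur]][2, ] else seg_p[[cur]][1, ]
      pts[[length(pts) + 1L]] <- p_in
      score <- score + sum((p_out - p_in) * cross3(n, fn[cur, ]))
      nxt <- setdiff(inc[[exit_key]], cur)
      if (length(nxt) != 1L) {
        abort("cross-section chaining failed (non-manifold cut)",
              class = "femtor_error_open_section")
      }
      if (nxt == start) break
      if (visited[nxt]) {
        abort("cross-section chaining failed (non-manifold cut)",
              class = "femtor_error_open_section")
      }
      at_key <- exit_key
      cur <- nxt
    }
    loop <- do.call(rbind, pts)
    if (score < 0) loop <- loop[rev(seq_len(nrow(loop))), , drop = FALSE]
    loops[[length(loops) + 1L]] <- loop
  }
  # in-plane basis
  e1 <- unitize(if (abs(n[1]) < 0.9) cross3(n, c(1, 0, 0)) else cross3(n, c(0, 1, 0)))
  e2 <- cross3(n, e1)
  origin <- plane$point
  areas <- numeric(length(loops))
  cents <- matrix(0, length(loops), 3)
  for (li in seq_along(loops)) {
    P <- sweep(loops[[li]], 2, origin)
    u <- P %*% e1
    v <- P %*% e2
    u2 <- c(u[-1], u[1])
    v2 <- c(v[-1], v[1])
    cr <- u * v2 - u2 * v
    a <- sum(cr) / 2
    areas[li] <- a
    if (abs(a) > 1e-12) {
      cu <- sum((u + u2) * cr) / (6 * a)
      cv <- sum((v + v2) * cr) / (6 * a)
    } else {
      cu <- mean(u); cv <- mean(v)
    }
    cents[li, ] <- origin + cu * e1 + cv * e2
  }
  total <- sum(areas)
  centroid <- if (abs(total) > 1e-12) {
    colSums(cents * areas) / total
  } else {
    colMeans(cents)
  }
  structure(list(plane = plane, loops = loops, loop_areas = areas,
                 area = abs(total), centroid = as.numeric(centroid),
                 largest_loop = which.max(abs(areas))),
            class = "fem_section")
}

#' @export
print.fem_section <- function(x, ...) {
  cat(sprintf("<cross-section> %d loop(s), area %.2f mm^2, centroid (%.3f, %.3f, %.3f) mm\n",
              length(x$loops), x$area, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# Area/centroid of a single loop (largest by default), used by neck/shaft
# constructions where only the main bone contour matters.
section_main_loop <- function(section) {
  li <- section$largest_loop
  list(points = section$loops[[li]],
       area = abs(section$loop_areas[li]),
       centroid = loop_centroid(section, li))
}

loop_centroid <- function(section, li) {
  n <- section$plane$normal
  e1 <- unitize(if (abs(n[1]) < 0.9) cross3(n, c(1, 0, 0)) else cross3(n, c(0, 1, 0)))
  e2 <- cross3(n, e1)
  origin <- section$plane$point
  P <- sweep(section$loops[[li]], 2, origin)
  u <- P %*% e1
  v <- P %*% e2
  u2 <- c(u[-1], u[1])
  v2 <- c(v[-1], v[1])
  cr <- u * v2 - u2 * v
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(section$loops[[li]]))
  cu <- sum((u + u2) * cr) / (6 * a)
  cv <- sum((v + v2) * cr) / (6 * a)
  as.numeric(origin + cu * e1 + cv * e2)
}
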
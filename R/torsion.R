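# The 3D torsion measurement pipeline: femoral head sphere, narrowest-neck
# cross-section, neck axis, posterior condylar tangent, anatomical femoral
# axis, and the projected signed angle.

#' Measurement parameters
#'
#' Captures the choices a reader makes interactively when measuring femoral
#' torsion on a surface model: the head patch for the sphere fit, the corridor
#' bracketing the femoral neck, the condylar/trochanteric landmark regions and
#' the trochanter tips, plus search tolerances. The axial (superior) and
#' posterior directions default to the LPS frame axes and are carried here so
#' that all constructions are explicit about the frame they use.
#'
#' @param head_region Integer vertex indices of the head patch on the proximal
#'   mesh (user-selected region on the femoral head).
#' @param corridor 2 x 3 matrix; two points bracketing the femoral neck, used
#'   both as the scan range and as the initial neck-axis estimate.
#' @param condyle_medial_seed,condyle_lateral_seed,trochanter_seed Length-3
#'   seed points; landmark regions are the mesh vertices within
#'   `region_radius` of each seed.
#' @param lesser_tip,greater_tip Length-3 landmark points, tips of the lesser
#'   and greater trochanter (set the proximal axial level).
#' @param region_radius Radius (mm) of the landmark regions.
#' @param distal_offset Height (mm) of the distal axial section above the top
#'   of the condylar region.
#' @param scan_step Plane spacing (mm) of the neck scan (<= 0.5 recommended).
#' @param centroid_tol Convergence tolerance (mm) on the neck centroid between
#'   axis re-estimation passes.
#' @param max_iter Cap on axis re-estimation passes.
#' @param axial_dir,posterior_dir Unit vectors defining "axial" (superior) and
#'   "posterior" (LPS defaults `c(0,0,1)` and `c(0,1,0)`). Override only when
#'   the meshes live in a rigidly transformed frame.
#' @param distal_level Optional absolute axial level (mm) for the distal
#'   section, overriding the condyle-top + offset rule.
#' @return A list of class `fem_measurement_params`.
#' @export
measurement_params <- function(head_region, corridor,
                               condyle_medial_seed, condyle_lateral_seed,
                               trochanter_seed = NULL,
                               lesser_tip, greater_tip,
                               region_radius = 16,
                               distal_offset = 10,
                               scan_step = 0.5,
                               centroid_tol = 0.1,
                               max_iter = 10L,
                               axial_dir = c(0, 0, 1),
                               posterior_dir = c(0, 1, 0),
                               distal_level = NULL) {
  corridor <- as.matrix(corridor)
  if (!all(dim(corridor) == c(2L, 3L))) {
    abort("corridor must be a 2 x 3 matrix of points", class = "femtor_error_parameter")
  }
  if (vnorm(corridor[2, ] - corridor[1, ]) < 1e-9) {
    abort("corridor endpoints must be distinct", class = "femtor_error_parameter")
  }
  if (distal_offset < 0 || scan_step <= 0 || region_radius <= 0) {
    abort("offsets must be >= 0 and step sizes > 0", class = "femtor_error_parameter")
  }
  structure(list(
    head_region = as.integer(head_region),
    corridor = corridor,
    condyle_medial_seed = vec3(condyle_medial_seed),
    condyle_lateral_seed = vec3(condyle_lateral_seed),
    trochanter_seed = if (!is.null(trochanter_seed)) vec3(trochanter_seed),
    lesser_tip = vec3(lesser_tip), greater_tip = vec3(greater_tip),
    region_radius = region_radius, distal_offset = distal_offset,
    scan_step = scan_step, centroid_tol = centroid_tol,
    max_iter = as.integer(max_iter),
    axial_dir = unitize(vec3(axial_dir), "axial direction"),
    posterior_dir = unitize(vec3(posterior_dir), "posterior direction"),
    distal_level = distal_level),
    class = "fem_measurement_params")
}

# in-plane point-in-polygon (even-odd) test; point and loop on section plane
loop_contains <- function(section, li, point) {
  n <- section$plane$normal
  e1 <- unitize(if (abs(n[1]) < 0.9) cross3(n, c(1, 0, 0)) else cross3(n, c(0, 1, 0)))
  e2 <- cross3(n, e1)
  P <- sweep(section$loops[[li]], 2, section$plane$point)
  u <- as.numeric(P %*% e1)
  v <- as.numeric(P %*% e2)
  q <- point - section$plane$point
  qu <- sum(q * e1)
  qv <- sum(q * e2)
  u2 <- c(u[-1], u[1])
  v2 <- c(v[-1], v[1])
  crosses <- ((v > qv) != (v2 > qv)) &
    (qu < (u2 - u) * (qv - v) / (v2 - v) + u)
  sum(crosses) %% 2L == 1L
}

# pick the loop of `section` enclosing `point`; smallest enclosing loop wins
select_loop_at <- function(section, point) {
  cand <- which(vapply(seq_along(section$loops), loop_contains,
                       logical(1), section = section, point = point))
  if (length(cand) == 0L) return(NULL)
  cand[which.min(abs(section$loop_areas[cand]))]
}

#' Narrowest femoral-neck cross-section
#'
#' Deterministic stand-in for the manual neck-plane fit: planes perpendicular
#' to the current neck-axis estimate are scanned along the corridor, the
#' minimum-area section through the neck is kept, and the axis estimate is
#' refreshed as the line from the head center to the current section centroid
#' until the centroid stabilises. The section loop containing the corridor
#' point is used, so slicing through the trochanter or head elsewhere on the
#' (infinite) plane does not disturb the search.
#'
#' @param mesh Proximal femur mesh.
#' @param corridor 2 x 3 matrix bracketing the neck (scan range).
#' @param params A [measurement_params()]; `scan_step`, `centroid_tol`,
#'   `max_iter` are used.
#' @param head_center Optional head center (mm) for axis re-estimation; if
#'   `NULL` the corridor direction is used throughout.
#' @return The minimizing [cross_section()], with fields `selected_loop`,
#'   `selected_area` (mm^2) and `selected_centroid` identifying the neck
#'   contour.
#' @export
find_narrowest_neck_plane <- function(mesh, corridor, params, head_center = NULL) {
  corridor <- as.matrix(corridor)
  p1 <- corridor[1, ]
  p2 <- corridor[2, ]
  axis_dir <- unitize(p2 - p1, "corridor direction")
  L <- vnorm(p2 - p1)
  offsets <- seq(0, L, by = params$scan_step)
  prev_centroid <- NULL
  best <- NULL
  for (iter in seq_len(params$max_iter)) {
    best <- NULL
    for (t in offsets) {
      q <- p1 + t * (p2 - p1) / L
      sec <- tryCatch(cross_section(mesh, plane3(q, axis_dir)),
                      error = function(e) NULL)
      if (is.null(sec)) next
      li <- select_loop_at(sec, q)
      if (is.null(li)) next
      a <- abs(sec$loop_areas[li])
      if (is.null(best) || a < best$area) {
        sec$selected_loop <- li
        sec$selected_area <- a
        sec$selected_centroid <- loop_centroid(sec, li)
        best <- list(section = sec, area = a)
      }
    }
    if (is.null(best)) {
      abort("no closed neck section found in the corridor",
            class = "femtor_error_measurement")
    }
    centroid <- best$section$selected_centroid
    if (is.null(head_center)) break
    new_dir <- unitize(head_center - centroid, "neck axis estimate")
    if (!is.null(prev_centroid) && vnorm(centroid - prev_centroid) < params$centroid_tol) {
      break
    }
    prev_centroid <- centroid
    axis_dir <- new_dir
  }
  best$section
}

#' Femoral neck axis
#'
#' The line from the centroid of the narrowest neck cross-section to the
#' femoral head center; the direction points towards the head.
#'
#' @param head A [fit_sphere()] result for the femoral head.
#' @param neck A neck cross-section (from [find_narrowest_neck_plane()] or
#'   [cross_section()]).
#' @return An [axis3()] anchored at the neck centroid.
#' @export
neck_axis <- function(head, neck) {
  stopifnot(inherits(head, "fem_sphere"), inherits(neck, "fem_section"))
  centroid <- neck$selected_centroid %||% neck$centroid
  if (vnorm(head$center - centroid) < 1e-9) {
    abort("head center coincides with the neck centroid",
          class = "femtor_error_degenerate")
  }
  axis3(centroid, head$center - centroid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Most posterior point of a landmark region
#'
#' Returns the vertex of `region` (indices into the mesh) that is extremal
#' along the posterior direction; ties are broken by the smallest vertex
#' index, so the result is deterministic.
#'
#' @param mesh A [fem_mesh()].
#' @param region Integer vertex indices (non-empty).
#' @param posterior_dir Posterior direction (LPS default `c(0, 1, 0)`).
#' @return Length-3 point (mm).
#' @export
posterior_extreme <- function(mesh, region, posterior_dir = c(0, 1, 0)) {
  region <- as.integer(region)
  if (length(region) == 0L) {
    abort("empty landmark region", class = "femtor_error_region")
  }
  y <- as.numeric(mesh$vertices[region, , drop = FALSE] %*% unitize(posterior_dir))
  idx <- region[y == max(y)]
  mesh$vertices[min(idx), ]
}

#' @rdname posterior_extreme
#' @param regions A list of three integer index vectors: medial condyle,
#'   lateral condyle, greater trochanter.
#' @return For `posterior_extremes()`: a 3 x 3 matrix of points (rows medial,
#'   lateral, trochanter).
#' @export
posterior_extremes <- function(mesh, regions, posterior_dir = c(0, 1, 0)) {
  stopifnot(is.list(regions), length(regions) == 3L)
  out <- t(vapply(regions, posterior_extreme, numeric(3),
                  mesh = mesh, posterior_dir = posterior_dir))
  rownames(out) <- c("medial", "lateral", "trochanter")
  out
}

#' Posterior condylar tangent
#'
#' The line through the most posterior points of the medial and lateral
#' femoral condyles, oriented medial to lateral.
#'
#' @param p_medial,p_lateral Length-3 points (mm).
#' @return An [axis3()].
#' @export
condylar_tangent <- function(p_medial, p_lateral) {
  p_medial <- vec3(p_medial)
  p_lateral <- vec3(p_lateral)
  if (vnorm(p_lateral - p_medial) < 1e-9) {
    abort("condylar points coincide", class = "femtor_error_degenerate")
  }
  axis3(p_medial, p_lateral - p_medial)
}

# axial cross-section centroid of the main (largest) loop at a given level
axial_centroid <- function(mesh, level, axial_dir, what) {
  bb <- range(as.numeric(mesh$vertices %*% axial_dir))
  if (level <= bb[1] || level >= bb[2]) {
    abort(sprintf("%s level %.1f mm is outside the mesh extent [%.1f, %.1f]",
                  what, level, bb[1], bb[2]),
          class = "femtor_error_level")
  }
  sec <- cross_section(mesh, plane3(level * axial_dir, axial_dir))
  section_main_loop(sec)$centroid
}

#' Anatomical femoral axis
#'
#' The line through the centroids of two axial shaft cross-sections: the
#' proximal one at the level midway between the tips of the lesser and
#' greater trochanter, the distal one just above the femoral condyles
#' (condyle-region top plus `distal_offset`, or an explicit `distal_level`).
#' Axial means a plane of constant superior coordinate; the direction points
#' proximal to distal.
#'
#' @param proximal,distal Proximal and distal femur meshes (may be the same
#'   mesh).
#' @param lesser_tip,greater_tip Trochanter tip landmarks (mm).
#' @param params A [measurement_params()] (uses `axial_dir`, `distal_offset`,
#'   `distal_level`, condyle seeds and `region_radius`).
#' @return An [axis3()] from the proximal to the distal centroid.
#' @export
anatomical_axis <- function(proximal, distal, lesser_tip, greater_tip, params) {
  ax <- params$axial_dir
  prox_level <- mean(c(sum(vec3(lesser_tip) * ax), sum(vec3(greater_tip) * ax)))
  if (!is.null(params$distal_level)) {
    dist_level <- params$distal_level
  } else {
    reg <- c(region_indices(distal, params$condyle_medial_seed, params$region_radius),
             region_indices(distal, params$condyle_lateral_seed, params$region_radius))
    if (length(reg) == 0L) {
      abort("condylar regions are empty on the distal mesh",
            class = "femtor_error_region")
    }
    top <- max(as.numeric(distal$vertices[reg, , drop = FALSE] %*% ax))
    dist_level <- top + params$distal_offset
  }
  c_prox <- axial_centroid(proximal, prox_level, ax, "proximal axial")
  c_dist <- axial_centroid(distal, dist_level, ax, "distal axial")
  if (vnorm(c_dist - c_prox) < 1e-9) {
    abort("anatomical axis endpoints coincide", class = "femtor_error_degenerate")
  }
  axis3(c_prox, c_dist - c_prox)
}

region_indices <- function(mesh, seed, radius) {
  d2 <- rowSums(sweep(mesh$vertices, 2, vec3(seed))^2)
  which(d2 <= radius^2)
}

#' Projected femoral torsion angle
#'
#' Projects the femoral neck axis and the posterior condylar tangent onto the
#' plane perpendicular to the anatomical femoral axis and returns the signed
#' angle between them in degrees, antetorsion positive for both sides (the
#' raw rotation sense about the anatomical axis is mirrored for right
#' femurs). Axes are treated as lines: the result is folded into (-90, 90].
#'
#' @param neck Neck axis ([axis3()], pointing towards the head).
#' @param condylar Condylar tangent ([axis3()], medial to lateral).
#' @param anatomical Anatomical axis ([axis3()], proximal to distal).
#' @param side `"left"` or `"right"`.
#' @return Angle in degrees.
#' @export
projected_torsion_angle <- function(neck, condylar, anatomical, side) {
  side <- match.arg(side, c("left", "right"))
  a <- anatomical$direction
  proj <- function(v, what) {
    w <- v - sum(v * a) * a
    if (vnorm(w) < 1e-9) {
      abort(sprintf("%s axis is parallel to the anatomical axis", what),
            class = "femtor_error_degenerate")
    }
    w / vnorm(w)
  }
  u <- proj(neck$direction, "neck")
  v <- proj(condylar$direction, "condylar")
  w <- -v                                   # medial sense of the tangent
  k <- if (side == "left") -a else a        # mirror handling between sides
  raw <- atan2(sum(k * cross3(w, u)), sum(w * u)) * 180 / pi
  if (raw > 90) raw <- raw - 180
  if (raw <= -90) raw <- raw + 180
  raw
}

#' Measure femoral torsion on a pair of surface meshes
#'
#' Runs the full 3D measurement: least-squares sphere fit on the selected
#' head patch, minimum-area neck cross-section, neck axis, posterior condylar
#' and trochanteric extreme points, posterior plane and condylar tangent,
#' anatomical axis from two axial shaft sections, and the projected signed
#' torsion angle. All intermediate landmarks are returned for audit.
#'
#' @param proximal,distal Proximal and distal femur meshes in the same frame
#'   and with the same side flag.
#' @param params A [measurement_params()].
#' @return An object of class `fem_torsion`; see [tidy.fem_torsion()] for a
#'   tabular summary. Fields include `angle_deg`, `head`, `neck_section`,
#'   `neck_axis`, `posterior_points`, `posterior_plane`, `condylar_tangent`,
#'   `anatomical_axis`, `side`.
#' @export
measure_torsion <- function(proximal, distal, params) {
  stopifnot(inherits(proximal, "fem_mesh"), inherits(distal, "fem_mesh"),
            inherits(params, "fem_measurement_params"))
  if (!identical(proximal$frame, distal$frame)) {
    abort("proximal and distal meshes must share the same frame and side",
          class = "femtor_error_frame")
  }
  side <- proximal$frame$side
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("torsion measurement failed at stage '%s': %s",
                    name, conditionMessage(e)),
            class = "femtor_error_measurement", parent = e)
    })
  }
  head <- stage("head sphere fit", {
    if (length(params$head_region) < 4L) {
      abort("head region has fewer than 4 vertices", class = "femtor_error_region")
    }
    fit_sphere(proximal$vertices[params$head_region, , drop = FALSE])
  })
  neck_sec <- stage("neck plane search",
    find_narrowest_neck_plane(proximal, params$corridor, params,
                              head_center = head$center))
  n_axis <- stage("neck axis", neck_axis(head, neck_sec))
  post <- stage("posterior extremes", {
    med <- region_indices(distal, params$condyle_medial_seed, params$region_radius)
    lat <- region_indices(distal, params$condyle_lateral_seed, params$region_radius)
    if (length(med) == 0L || length(lat) == 0L) {
      abort("empty condylar region", class = "femtor_error_region")
    }
    p_med <- posterior_extreme(distal, med, params$posterior_dir)
    p_lat <- posterior_extreme(distal, lat, params$posterior_dir)
    p_gt <- if (!is.null(params$trochanter_seed)) {
      gt <- region_indices(proximal, params$trochanter_seed, params$region_radius)
      if (length(gt) == 0L) {
        abort("empty trochanter region", class = "femtor_error_region")
      }
      posterior_extreme(proximal, gt, params$posterior_dir)
    }
    list(medial = p_med, lateral = p_lat, trochanter = p_gt)
  })
  tangent <- stage("condylar tangent", condylar_tangent(post$medial, post$lateral))
  posterior_plane <- if (!is.null(post$trochanter)) {
    nrm <- cross3(post$lateral - post$medial, post$trochanter - post$medial)
    if (vnorm(nrm) > 1e-9) plane3(post$medial, nrm)
  }
  a_axis <- stage("anatomical axis",
    anatomical_axis(proximal, distal, params$lesser_tip, params$greater_tip,
                    params))
  angle <- stage("projected angle",
    projected_torsion_angle(n_axis, tangent, a_axis, side))
  structure(list(
    angle_deg = angle, side = side,
    head = head, neck_section = neck_sec, neck_axis = n_axis,
    posterior_points = post, posterior_plane = posterior_plane,
    condylar_tangent = tangent, anatomical_axis = a_axis,
    params = params),
    class = "fem_torsion")
}

#' @export
print.fem_torsion <- function(x, ...) {
  cat(sprintf("<torsion measurement> %s femur: %.2f deg (antetorsion positive)\n",
              x$side, x$angle_deg))
  cat(sprintf("  head center (%.2f, %.2f, %.2f) mm, radius %.2f mm (rms %.3f mm)\n",
              x$head$center[1], x$head$center[2], x$head$center[3],
              x$head$radius, x$head$rms_residual))
  cat(sprintf("  neck isthmus area %.1f mm^2, centroid (%.2f, %.2f, %.2f) mm\n",
              x$neck_section$selected_area %||% x$neck_section$area,
              x$neck_section$selected_centroid[1] %||% NA,
              x$neck_section$selected_centroid[2] %||% NA,
              x$neck_section$selected_centroid[3] %||% NA))
  invisible(x)
}

#' Tidy a torsion measurement
#'
#' @param x A `fem_torsion` object.
#' @param ... Unused.
#' @return A one-row tibble with the angle, side, head sphere parameters,
#'   neck isthmus area and landmark coordinates.
#' @export
tidy.fem_torsion <- function(x, ...) {
  tibble::tibble(
    side = x$side,
    angle_deg = x$angle_deg,
    head_radius_mm = x$head$radius,
    head_rms_mm = x$head$rms_residual,
    neck_area_mm2 = x$neck_section$selected_area %||% x$neck_section$area,
    head_x = x$head$center[1], head_y = x$head$center[2], head_z = x$head$center[3],
    neck_x = (x$neck_section$selected_centroid %||% x$neck_section$centroid)[1],
    neck_y = (x$neck_section$selected_centroid %||% x$neck_section$centroid)[2],
    neck_z = (x$neck_section$selected_centroid %||% x$neck_section$centroid)[3])
}

#' Serialize a torsion measurement
#'
#' Writes the measurement with all intermediate landmarks to JSON, or a
#' one-row CSV suitable for assembling measurement tables.
#'
#' @param x A `fem_torsion` object.
#' @param path Output path.
#' @param subject,reader,modality Identifiers recorded in the CSV row.
#' @return `path`, invisibly.
#' @export
write_torsion_json <- function(x, path) {
  stopifnot(inherits(x, "fem_torsion"))
  out <- list(
    angle_deg = x$angle_deg, side = x$side,
    head = list(center = x$head$center, radius = x$head$radius,
                rms_residual = x$head$rms_residual),
    neck = list(centroid = x$neck_section$selected_centroid %||% x$neck_section$centroid,
                area_mm2 = x$neck_section$selected_area %||% x$neck_section$area,
                plane_point = x$neck_section$plane$point,
                plane_normal = x$neck_section$plane$normal),
    neck_axis = list(point = x$neck_axis$point, direction = x$neck_axis$direction),
    posterior_points = x$posterior_points,
    posterior_plane = if (!is.null(x$posterior_plane)) {
      list(point = x$posterior_plane$point, normal = x$posterior_plane$normal)
    },
    condylar_tangent = list(point = x$condylar_tangent$point,
                            direction = x$condylar_tangent$direction),
    anatomical_axis = list(point = x$anatomical_axis$point,
                           direction = x$anatomical_axis$direction))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_torsion_json
#' @export
write_torsion_csv <- function(x, path, subject = NA, reader = NA, modality = NA) {
  stopifnot(inherits(x, "fem_torsion"))
  row <- dplyr::mutate(tidy(x), subject = subject, reader = reader,
                       modality = modality, .before = 1)
  utils::write.csv(row, path, row.names = FALSE)
  invisible(path)
}
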
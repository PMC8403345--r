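section_stub <- function(centroid) {
  s <- structure(list(plane = plane3(centroid, c(0, 0, 1)),
                      loops = list(), loop_areas = numeric(0),
                      area = 1, centroid = centroid, largest_loop = 1L),
                 class = "fem_section")
  s
}

sphere_stub <- function(center) {
  structure(list(center = center, radius = 10, rms_residual = 0),
            class = "fem_sphere")
}

test_that("neck axis points from the neck centroid to the head center", {
  a <- neck_axis(sphere_stub(c(0, 0, 10)), section_stub(c(0, 0, 0)))
  expect_equal(a$direction, c(0, 0, 1))
  expect_equal(a$point, c(0, 0, 0))
  b <- neck_axis(sphere_stub(c(3, 4, 0)), section_stub(c(0, 0, 0)))
  expect_equal(b$direction, c(0.6, 0.8, 0))
  expect_error(neck_axis(sphere_stub(c(1, 2, 3)), section_stub(c(1, 2, 3))),
               class = "femtor_error_degenerate")
})

test_that("posterior extremes maximize the posterior coordinate with a deterministic tie rule", {
  fr <- anatomical_frame("right")
  v <- rbind(c(0, 1, 0), c(1, 5, 0), c(2, 2, 0), c(0, 5, 1))
  m <- fem_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4)), fr)
  expect_equal(posterior_extreme(m, 1:3), c(1, 5, 0))
  # tie between vertices 2 and 4 (both y = 5): lowest index wins
  expect_equal(posterior_extreme(m, 1:4), c(1, 5, 0))
  expect_equal(posterior_extreme(m, c(4, 2)), c(1, 5, 0))
  expect_error(posterior_extreme(m, integer(0)), class = "femtor_error_region")
})

test_that("condylar tangent is oriented medial to lateral", {
  t <- condylar_tangent(c(0, 0, 0), c(10, 0, 0))
  expect_equal(t$direction, c(1, 0, 0))
  expect_error(condylar_tangent(c(1, 1, 1), c(1, 1, 1)),
               class = "femtor_error_degenerate")
})

test_that("projected angle satisfies its defining constructions on both sides", {
  anat <- axis3(c(0, 0, 100), c(0, 0, -1))   # proximal -> distal = inferior
  # neck projection parallel to the condylar medial sense: 0 degrees
  for (side in c("right", "left")) {
    mx <- if (side == "right") 1 else -1
    cond <- axis3(c(0, 0, 0), c(mx, 0, 0) * -1)      # medial -> lateral
    neck <- axis3(c(0, 0, 0), c(mx, 0, 0.5))         # medial + superior
    expect_equal(projected_torsion_angle(neck, cond, anat, side), 0,
                 tolerance = 1e-9)
    # neck perpendicular, tilted anteriorly: +90
    neck_ant <- axis3(c(0, 0, 0), c(0, -1, 0.5))
    expect_equal(projected_torsion_angle(neck_ant, cond, anat, side), 90,
                 tolerance = 1e-9)
    # rotating the condylar tangent about the anatomical axis in the anterior
    # sense by 17.3 degrees must measure exactly 17.3 on either side
    sense <- if (side == "right") 1 else -1
    R <- femtor:::rotation_about(c(0, 0, -1), sense * 17.3 * pi / 180)
    neck_rot <- axis3(c(0, 0, 0), as.numeric(R %*% cond$direction))
    expect_equal(projected_torsion_angle(neck_rot, cond, anat, side), 17.3,
                 tolerance = 1e-9)
  }
})

test_that("projection degenerates when an axis is parallel to the anatomical axis", {
  anat <- axis3(c(0, 0, 0), c(0, 0, 1))
  cond <- axis3(c(0, 0, 0), c(1, 0, 0))
  neck <- axis3(c(0, 0, 0), c(0, 0, 1))
  expect_error(projected_torsion_angle(neck, cond, anat, "right"),
               class = "femtor_error_degenerate")
})

test_that("anatomical axis of an ideal vertical shaft is the superior-inferior line", {
  cyl <- mesh_cylinder(radius = 15, height = 200, n_seg = 96, n_z = 40,
                       frame = anatomical_frame("right"))
  params <- measurement_params(
    head_region = 1:4, corridor = rbind(c(0, 0, 0), c(0, 0, 1)),
    condyle_medial_seed = c(0, 0, 0), condyle_lateral_seed = c(0, 0, 0),
    lesser_tip = c(0, 0, 120), greater_tip = c(0, 0, 160),
    distal_level = 30)
  ax <- anatomical_axis(cyl, cyl, c(0, 0, 120), c(0, 0, 160), params)
  expect_equal(ax$direction, c(0, 0, -1), tolerance = 1e-9)
  # requested level above the mesh top
  params_bad <- measurement_params(
    head_region = 1:4, corridor = rbind(c(0, 0, 0), c(0, 0, 1)),
    condyle_medial_seed = c(0, 0, 0), condyle_lateral_seed = c(0, 0, 0),
    lesser_tip = c(0, 0, 120), greater_tip = c(0, 0, 160),
    distal_level = 250)
  expect_error(anatomical_axis(cyl, cyl, c(0, 0, 120), c(0, 0, 160), params_bad),
               class = "femtor_error_level")
})

test_that("the narrowest-plane search finds a hyperboloid waist", {
  # r(z)^2 = r0^2 + (c z)^2: waist at z = 0 exactly
  hyp <- mesh_revolution(function(z) sqrt(12^2 + (0.45 * z)^2),
                         z_range = c(-25, 25), n_seg = 128, n_z = 100,
                         frame = anatomical_frame("right"))
  params <- measurement_params(
    head_region = 1:4, corridor = rbind(c(0, 0, -15), c(0, 0, 15)),
    condyle_medial_seed = c(0, 0, 0), condyle_lateral_seed = c(0, 0, 0),
    lesser_tip = c(0, 0, 0), greater_tip = c(0, 0, 1),
    scan_step = 0.25)
  sec <- find_narrowest_neck_plane(hyp, params$corridor, params)
  expect_lt(abs(sec$selected_centroid[3]), 0.5)
  expect_lt(abs(sec$selected_area - pi * 144) / (pi * 144), 0.02)
})

test_that("a corridor outside the mesh is a measurement failure", {
  cyl <- mesh_cylinder(radius = 5, height = 10, frame = anatomical_frame("right"))
  params <- measurement_params(
    head_region = 1:4, corridor = rbind(c(100, 100, 0), c(100, 100, 10)),
    condyle_medial_seed = c(0, 0, 0), condyle_lateral_seed = c(0, 0, 0),
    lesser_tip = c(0, 0, 2), greater_tip = c(0, 0, 8))
  expect_error(find_narrowest_neck_plane(cyl, params$corridor, params),
               class = "femtor_error_measurement")
})

test_that("the neck search matches a dense offset/tilt brute-force oracle", {
  fem <- cached_femur(pitch = 1.8)
  truth <- fem$truth
  params <- params_from_ground_truth(fem$truth, fem$proximal)
  sec <- find_narrowest_neck_plane(fem$proximal, params$corridor, params,
                                   head_center = truth$head_center)
  # oracle: dense scan over plane offset and +-10 degree tilts about two
  # in-plane axes
  dir0 <- truth$neck_dir
  e1 <- pracma::cross(dir0, c(0, 0, 1)); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma::cross(dir0, e1)
  best <- Inf
  for (t1 in seq(-10, 10, by = 5)) {
    for (t2 in seq(-10, 10, by = 5)) {
      R <- femtor:::rotation_about(e1, t1 * pi / 180) %*%
        femtor:::rotation_about(e2, t2 * pi / 180)
      nrm <- as.numeric(R %*% dir0)
      for (off in seq(0, 1, by = 0.0625)) {
        q <- truth$corridor[1, ] + off * (truth$corridor[2, ] - truth$corridor[1, ])
        s <- tryCatch(cross_section(fem$proximal, plane3(q, nrm)),
                      error = function(e) NULL)
        if (is.null(s)) next
        li <- femtor:::select_loop_at(s, q)
        if (is.null(li)) next
        a <- abs(s$loop_areas[li])
        if (a < best) best <- a
      }
    }
  }
  expect_lt(abs(sec$selected_area - best) / best, 0.02)
})
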
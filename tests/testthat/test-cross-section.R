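test_that("cube section is a unit square with centroid on the plane", {
  cube <- mesh_cube(frame = anatomical_frame("right"))
  s <- cross_section(cube, plane3(c(0.5, 0.5, 0.5), c(0, 0, 1)))
  expect_length(s$loops, 1)
  expect_equal(s$area, 1.0, tolerance = 1e-12)
  expect_equal(s$centroid, c(0.5, 0.5, 0.5), tolerance = 1e-12)
  # centroid lies on the plane
  expect_lt(abs(sum((s$centroid - s$plane$point) * s$plane$normal)), 1e-6)
})

test_that("cylinder section area matches the closed form within 1%", {
  cyl <- mesh_cylinder(radius = 10, height = 40, n_seg = 160, n_z = 30,
                       frame = anatomical_frame("right"))
  expect_gt(nrow(cyl$faces), 9000)
  s <- cross_section(cyl, plane3(c(0, 0, 17.3), c(0, 0, 1)))
  expect_lt(abs(s$area - pi * 100) / (pi * 100), 0.01)
  expect_equal(s$centroid[1:2], c(0, 0), tolerance = 1e-9)
})

test_that("disjoint solids yield one loop each with positive enclosed area", {
  fr <- anatomical_frame("right")
  a <- mesh_icosphere(radius = 5, center = c(0, 0, 0), subdivisions = 3, frame = fr)
  two <- fem_mesh(rbind(a$vertices, sweep(a$vertices, 2, c(20, 0, 0), "+")),
                  rbind(a$faces, a$faces + nrow(a$vertices)), fr)
  s <- cross_section(two, plane3(c(0, 0, 0), c(0, 0, 1)))
  expect_length(s$loops, 2)
  expect_true(all(s$loop_areas > 0))
  expect_equal(s$area, sum(s$loop_areas), tolerance = 1e-12)
})

test_that("missing or open cuts raise typed errors", {
  cyl <- mesh_cylinder(radius = 5, height = 10, frame = anatomical_frame("left"))
  expect_error(cross_section(cyl, plane3(c(0, 0, 50), c(0, 0, 1))),
               class = "femtor_error_empty_section")
  holed <- cyl
  fz <- cbind(holed$vertices[holed$faces[, 1], 3],
              holed$vertices[holed$faces[, 2], 3],
              holed$vertices[holed$faces[, 3], 3])
  drop_face <- which(apply(fz, 1, function(z) diff(range(z)) > 0.5))[1]
  zc <- mean(range(fz[drop_face, ]))
  holed$faces <- holed$faces[-drop_face, , drop = FALSE]
  expect_error(cross_section(holed, plane3(c(0, 0, zc), c(0, 0, 1))),
               class = "femtor_error_open_section")
})

test_that("femur neck cut centroid matches the SDF voxel oracle", {
  fem <- cached_femur(pitch = 1.8)
  truth <- fem$truth
  geom <- femtor:::femur_geometry(
    femur_params(theta = truth$theta, side = truth$side, pitch = 1.8))
  q <- colMeans(truth$corridor)
  s <- cross_section(fem$proximal, plane3(q, truth$neck_dir))
  li <- femtor:::select_loop_at(s, q)
  centroid <- femtor:::loop_centroid(s, li)
  oracle <- sdf_plane_centroid_oracle(geom$field, q, truth$neck_dir, q,
                                      radius = 1.5 * truth$neck_radius)
  expect_lt(sqrt(sum((centroid - oracle)^2)), 0.5)
})
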
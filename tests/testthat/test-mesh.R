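test_that("construction deduplicates vertices and drops degenerate faces", {
  fr <- anatomical_frame("right")
  # triangle soup of a cube face pair: shared vertices repeated per triangle
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
             c(0, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), c(1, 1, 1))  # degenerate
  f <- matrix(1:9, ncol = 3, byrow = TRUE)
  m <- fem_mesh(v, f, fr)
  expect_equal(nrow(m$vertices), 6)
  expect_equal(nrow(m$faces), 2)
})

test_that("construction rejects empty meshes, bad indices and bad frames", {
  fr <- anatomical_frame("left")
  expect_error(fem_mesh(matrix(0, 0, 3), matrix(1L, 0, 3), fr),
               class = "femtor_error_empty")
  expect_error(fem_mesh(diag(3), rbind(c(1, 2, 4)), fr),
               class = "femtor_error_format")
  expect_error(fem_mesh(diag(3), rbind(c(1, 2, 3)), frame = "LPS"),
               class = "femtor_error_frame")
  expect_error(anatomical_frame("right", convention = "RAS"),
               class = "femtor_error_frame")
})

test_that("diagnostics report watertightness, components and bounding box", {
  fr <- anatomical_frame("right")
  ico <- mesh_icosphere(radius = 10, subdivisions = 2, frame = fr)
  d <- validate_mesh(ico)
  expect_true(d$watertight)
  expect_equal(d$n_components, 1)
  expect_equal(c(d$x_min, d$x_max), c(-10, 10), tolerance = 1e-6)

  holed <- ico
  holed$faces <- holed$faces[-1, , drop = FALSE]
  dh <- validate_mesh(holed)
  expect_false(dh$watertight)
  expect_equal(dh$n_boundary_edges, 3)

  two <- fem_mesh(rbind(ico$vertices, sweep(ico$vertices, 2, c(30, 0, 0), "+")),
                  rbind(ico$faces, ico$faces + nrow(ico$vertices)), fr)
  expect_equal(validate_mesh(two)$n_components, 2)
})

test_that("diagnostics are deterministic and leave the mesh unmodified", {
  m <- mesh_cylinder(radius = 5, height = 20, frame = anatomical_frame("left"))
  before <- m
  d1 <- validate_mesh(m)
  d2 <- validate_mesh(m)
  expect_identical(d1, d2)
  expect_identical(m, before)
})

test_that("reflection transforms preserve orientation consistency", {
  m <- mesh_icosphere(radius = 5, subdivisions = 2,
                      frame = anatomical_frame("right"))
  mm <- mirror_mesh(m, x0 = 2)
  expect_true(validate_mesh(mm)$watertight)
  expect_equal(mm$frame$side, "left")
  # mirrored x about x0 = 2; y, z unchanged
  expect_equal(sort(mm$vertices[, 1]), sort(4 - m$vertices[, 1]))
  expect_equal(mm$vertices[, 2:3], m$vertices[, 2:3])
})
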
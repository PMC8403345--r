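test_that("a cube survives the STL round trip in both flavours", {
  fr <- anatomical_frame("right")
  cube <- mesh_cube(frame = fr)
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_mesh(cube, path, binary = binary)
    back <- read_mesh(path, fr)
    expect_equal(nrow(back$vertices), 8)
    expect_equal(nrow(back$faces), 12)
    # same vertex set within 1e-6 mm
    ord <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
    expect_equal(ord(back$vertices), ord(cube$vertices), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("ASCII STL and PLY round trips preserve coordinates to 1e-6 mm", {
  fr <- anatomical_frame("left")
  m <- mesh_icosphere(radius = 7.31, center = c(103.2, -45.7, 338.1),
                      subdivisions = 2, frame = fr)
  for (ext in c(".stl", ".ply")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(m, path, binary = FALSE)
    back <- read_mesh(path, fr)
    expect_equal(nrow(back$faces), nrow(m$faces))
    ord <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
    expect_lt(max(abs(ord(back$vertices) - ord(m$vertices))), 1e-6)
  }
})

test_that("a synthetic femur written to PLY rereads with equal topology", {
  fem <- cached_femur(pitch = 2.5)
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(fem$distal, path)
  back <- read_mesh(path, fem$distal$frame)
  expect_equal(nrow(back$faces), nrow(fem$distal$faces))
  expect_equal(nrow(back$vertices), nrow(fem$distal$vertices))
  expect_lt(max(abs(back$vertices - fem$distal$vertices)), 1e-6)
})

test_that("unreadable, corrupt and unsupported files raise typed errors", {
  fr <- anatomical_frame("right")
  expect_error(read_mesh("no/such/file.stl", fr), class = "femtor_error_io")
  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines("solid junk\nnot a facet", bad)
  expect_error(read_mesh(bad, fr), class = "femtor_error_format")
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines("v 0 0 0", obj)
  expect_error(read_mesh(obj, fr), class = "femtor_error_format")
  badply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_little_endian 1.0", "end_header"), badply)
  expect_error(read_mesh(badply, fr), class = "femtor_error_format")
  # write failure surfaces as an I/O error
  expect_error(write_mesh(mesh_cube(frame = fr), "no/such/dir/cube.stl"),
               class = "femtor_error_io")
})
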
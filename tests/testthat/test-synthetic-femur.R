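test_that("parameter validation rejects impossible anatomies", {
  expect_error(femur_params(theta = 200), class = "femtor_error_parameter")
  expect_error(femur_params(head_radius = -1), class = "femtor_error_parameter")
  expect_error(femur_params(pitch = 0), class = "femtor_error_parameter")
  expect_error(femur_params(noise_sd = -0.1), class = "femtor_error_parameter")
  expect_error(femur_params(neck_shaft_angle = 80), class = "femtor_error_parameter")
})

test_that("noise-free femur segments are watertight single components", {
  fem <- cached_femur(pitch = 1.8)
  for (m in list(fem$proximal, fem$distal)) {
    d <- validate_mesh(m)
    expect_true(d$watertight)
    expect_equal(d$n_components, 1)
    expect_equal(d$n_degenerate, 0)
  }
})

test_that("generation is deterministic for a fixed seed, including noise", {
  p <- femur_params(theta = 15, noise_sd = 0.5, pitch = 2.5, seed = 42L)
  a <- generate_femur(p)
  b <- generate_femur(p)
  expect_identical(a$proximal$vertices, b$proximal$vertices)
  expect_identical(a$distal$faces, b$distal$faces)
  c_ <- generate_femur(femur_params(theta = 15, noise_sd = 0.5, pitch = 2.5,
                                    seed = 43L))
  expect_false(identical(a$proximal$vertices, c_$proximal$vertices))
})

test_that("posterior condylar apices sit where the generator placed them", {
  fem <- cached_femur(pitch = 1.8)
  truth <- fem$truth
  for (apex in list(truth$condyle_apex_medial, truth$condyle_apex_lateral)) {
    reg <- femtor:::region_indices(fem$distal, apex, 16)
    p <- posterior_extreme(fem$distal, reg)
    expect_lt(sqrt(sum((p - apex)^2)), 1.0)
  }
})

test_that("at zero torsion the measured condylar tangent is perpendicular to the sagittal plane", {
  fem <- cached_femur(theta = 0, pitch = 1.8)
  med <- femtor:::region_indices(fem$distal, fem$truth$condyle_apex_medial, 16)
  lat <- femtor:::region_indices(fem$distal, fem$truth$condyle_apex_lateral, 16)
  tng <- condylar_tangent(posterior_extreme(fem$distal, med),
                          posterior_extreme(fem$distal, lat))
  ang <- acos(min(1, abs(tng$direction[1]))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("ground truth is sufficient to drive the full measurement", {
  fem <- cached_femur(pitch = 1.8)
  m <- measure_femur(fem)
  expect_s3_class(m, "fem_torsion")
  expect_true(is.finite(m$angle_deg))
  expect_lt(abs(m$angle_deg - fem$truth$theta), 1.0)
  # head sphere recovered from the surface patch
  expect_lt(sqrt(sum((m$head$center - fem$truth$head_center)^2)), 0.25)
  expect_lt(abs(m$head$radius - fem$truth$head_radius), 0.25)
})
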
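# Synthetic femur generator. A femur-like solid is assembled as the smooth
# union of signed-distance primitives (shaft, neck, head, condyles,
# trochanters) so that the true torsion angle is known by construction: the
# posterior apices of the two condylar ellipsoids sit at equal posterior
# coordinate, making the condylar tangent the 0-degree reference, and the neck
# is rotated about the shaft axis by exactly the requested torsion.

#' Parameters of the synthetic femur
#'
#' Defaults approximate an adult femur in mm. The torsion `theta` rotates the
#' neck about the shaft (z) axis, anterior rotation positive (antetorsion),
#' identically for both sides. `noise_sd` adds isotropic Gaussian jitter to
#' the extracted surface vertices, emulating the coarser osseous morphology of
#' MRI-based segmentations; `pitch` is the isosurface sampling pitch.
#'
#' @param theta True torsion in degrees, in (-180, 180].
#' @param side `"left"` or `"right"`.
#' @param neck_shaft_angle Neck-shaft angle in degrees (angle between neck
#'   axis and shaft axis).
#' @param head_radius,neck_radius,neck_length,shaft_radius Radii/length in mm.
#' @param condyle_semi Length-3 semi-axes of each condylar ellipsoid (mm).
#' @param condyle_spacing Distance of each condyle center from the sagittal
#'   midplane (mm).
#' @param noise_sd Vertex noise standard deviation (mm).
#' @param pitch Isosurface voxel pitch (mm).
#' @param blend Smooth-union blending radius between primitives (mm).
#' @param seed Integer seed for the vertex noise.
#' @return A list of class `fem_femur_params`.
#' @export
femur_params <- function(theta = 15, side = c("right", "left"),
                         neck_shaft_angle = 128, head_radius = 24,
                         neck_radius = 14, neck_length = 60,
                         shaft_radius = 15,
                         condyle_semi = c(18, 27, 24), condyle_spacing = 23,
                         noise_sd = 0, pitch = 1.0, blend = 3, seed = 1L) {
  side <- match.arg(side)
  if (!is.finite(theta) || theta <= -180 || theta > 180) {
    abort("theta must be in (-180, 180]", class = "femtor_error_parameter")
  }
  vals <- c(head_radius, neck_radius, neck_length, shaft_radius,
            condyle_semi, condyle_spacing, pitch, blend)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all femur dimensions and the pitch must be positive",
          class = "femtor_error_parameter")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "femtor_error_parameter")
  }
  if (neck_shaft_angle <= 90 || neck_shaft_angle >= 180) {
    abort("neck_shaft_angle must be in (90, 180) degrees",
          class = "femtor_error_parameter")
  }
  structure(list(theta = theta, side = side,
                 neck_shaft_angle = neck_shaft_angle,
                 head_radius = head_radius, neck_radius = neck_radius,
                 neck_length = neck_length, shaft_radius = shaft_radius,
                 condyle_semi = condyle_semi, condyle_spacing = condyle_spacing,
                 noise_sd = noise_sd, pitch = pitch, blend = blend,
                 seed = as.integer(seed)),
            class = "fem_femur_params")
}

#' Generate a synthetic femur with known torsion
#'
#' Builds proximal and distal femur segments (the regions a clinical torsion
#' protocol scans) as isosurfaces of a smooth-union signed distance field and
#' returns them with a ground-truth record sufficient to run
#' [measure_torsion()] with no manual input.
#'
#' @param params A [femur_params()] object.
#' @return A list with elements `proximal` and `distal` ([fem_mesh()]) and
#'   `truth`, a list holding the true torsion, head sphere, neck axis and
#'   corridor, condylar apices, trochanter tips and landmark seeds.
#' @export
#' @examples
#' \donttest{
#' fem <- generate_femur(femur_params(theta = 15, pitch = 2))
#' fem$truth$theta
#' }
generate_femur <- function(params) {
  stopifnot(inherits(params, "fem_femur_params"))
  p <- params
  geom <- femur_geometry(p)
  frame <- anatomical_frame(p$side)
  proximal <- sdf_mesh(
    function(P) sdf_intersect(geom$field(P),
                              sdf_halfspace(P, c(0, 0, 1), geom$prox_cut)),
    geom$prox_x, geom$prox_y, geom$prox_z, p$pitch, frame)
  distal <- sdf_mesh(
    function(P) sdf_intersect(geom$field(P),
                              sdf_halfspace(P, c(0, 0, -1), -geom$dist_cut)),
    geom$dist_x, geom$dist_y, geom$dist_z, p$pitch, frame)

  if (p$noise_sd > 0) {
    withr::with_seed(p$seed, {
      proximal$vertices <- proximal$vertices +
        matrix(rnorm(length(proximal$vertices), sd = p$noise_sd),
               ncol = 3)
      distal$vertices <- distal$vertices +
        matrix(rnorm(length(distal$vertices), sd = p$noise_sd), ncol = 3)
    })
  }

  list(proximal = proximal, distal = distal, truth = geom$truth)
}

# Geometric layout of the synthetic femur: primitive placement, the signed
# distance field, grid extents of the two scan segments, and the ground-truth
# record. Shared by generate_femur() and by validation oracles that need the
# generating field itself.
femur_geometry <- function(p) {
  mx <- if (p$side == "right") 1 else -1   # medial direction sign along +x
  alpha <- (180 - p$neck_shaft_angle) * pi / 180  # neck elevation from vertical
  theta <- p$theta * pi / 180
  shaft_a <- c(0, 0, 30)
  shaft_b <- c(0, 0, 425)
  neck_base <- c(0, 0, 405)
  # neck direction: medial and superior, rotated anteriorly (-y) by theta
  neck_dir <- c(mx * sin(alpha) * cos(theta), -sin(alpha) * sin(theta), cos(alpha))
  head_center <- neck_base + p$neck_length * neck_dir
  cond_medial <- c(mx * p$condyle_spacing, 8, 25)
  cond_lateral <- c(-mx * p$condyle_spacing, 8, 25)
  gt_center <- c(-mx * 22, 4, 420)
  gt_semi <- c(11, 13, 15)
  lt_center <- c(mx * 9, 11, 370)
  lt_semi <- c(8, 8, 11)
  field <- function(P) {
    f <- sdf_capsule(P, shaft_a, shaft_b, p$shaft_radius)
    f <- smin(f, sdf_capsule(P, neck_base, head_center, p$neck_radius), p$blend)
    f <- smin(f, sdf_sphere(P, head_center, p$head_radius), p$blend)
    f <- smin(f, sdf_ellipsoid(P, cond_medial, p$condyle_semi), p$blend)
    f <- smin(f, sdf_ellipsoid(P, cond_lateral, p$condyle_semi), p$blend)
    f <- smin(f, sdf_ellipsoid(P, gt_center, gt_semi), p$blend)
    f <- smin(f, sdf_ellipsoid(P, lt_center, lt_semi), p$blend)
    f
  }
  margin <- 4
  head_reach <- vnorm(head_center[1:2]) + p$head_radius + margin
  prox_cut <- 356
  dist_cut <- 72
  cw <- p$condyle_spacing + p$condyle_semi[1] + margin
  truth <- list(
    theta = p$theta, side = p$side,
    head_center = head_center, head_radius = p$head_radius,
    neck_base = neck_base, neck_dir = neck_dir, neck_length = p$neck_length,
    neck_radius = p$neck_radius,
    corridor = rbind(neck_base + 24 * neck_dir, neck_base + 32 * neck_dir),
    condyle_apex_medial = cond_medial + c(0, p$condyle_semi[2], 0),
    condyle_apex_lateral = cond_lateral + c(0, p$condyle_semi[2], 0),
    gt_posterior = gt_center + c(0, gt_semi[2], 0),
    greater_tip = gt_center + c(0, 0, gt_semi[3]),
    lesser_tip = lt_center + c(0, 0, lt_semi[3]),
    condyle_top_z = cond_medial[3] + p$condyle_semi[3],
    shaft_axis = axis3(c(0, 0, 200), c(0, 0, 1)))
  list(field = field, truth = truth,
       prox_cut = prox_cut, dist_cut = dist_cut,
       prox_x = range(c(-head_reach, head_reach,
                        gt_center[1] + c(-1, 1) * (gt_semi[1] + margin))),
       prox_y = range(c(-head_reach, head_reach,
                        gt_center[2] + c(-1, 1) * (gt_semi[2] + margin),
                        lt_center[2] + c(-1, 1) * (lt_semi[2] + margin))),
       prox_z = c(prox_cut - 2, head_center[3] + p$head_radius + margin),
       dist_x = c(-cw, cw),
       dist_y = c(8 - p$condyle_semi[2] - margin, 8 + p$condyle_semi[2] + margin),
       dist_z = c(25 - p$condyle_semi[3] - margin, dist_cut + 2))
}

#' Measurement parameters from synthetic ground truth
#'
#' Builds a complete [measurement_params()] object from the ground-truth
#' record of [generate_femur()], standing in for the interactive landmark
#' choices a human reader makes (head patch selection, neck corridor,
#' condylar/trochanteric regions, trochanter tips).
#'
#' @param truth The `truth` element returned by [generate_femur()].
#' @param proximal The proximal segment mesh (used to select the head patch).
#' @param head_band Half-width (mm) of the radial band of vertices accepted
#'   as the femoral head patch.
#' @return A [measurement_params()] object.
#' @export
params_from_ground_truth <- function(truth, proximal, head_band = 2.0) {
  d <- sweep(proximal$vertices, 2, truth$head_center)
  r <- sqrt(rowSums(d^2))
  along <- as.numeric(d %*% truth$neck_dir)
  head_region <- which(abs(r - truth$head_radius) < head_band &
                         along > -0.1 * truth$head_radius)
  measurement_params(
    head_region = head_region,
    corridor = truth$corridor,
    condyle_medial_seed = truth$condyle_apex_medial,
    condyle_lateral_seed = truth$condyle_apex_lateral,
    trochanter_seed = truth$gt_posterior,
    lesser_tip = truth$lesser_tip,
    greater_tip = truth$greater_tip)
}
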
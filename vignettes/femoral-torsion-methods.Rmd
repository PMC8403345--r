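---
title: "Measuring 3D femoral torsion on surface models: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D femoral torsion on surface models: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femtor)
```

## The measurement model

Femoral torsion is the twist of the femoral neck relative to the knee,
measured in the axial plane. `femtor` implements the surface-model
definition used in clinical 3D planning: the angle between the **femoral
neck axis** and the **posterior condylar tangent**, both projected onto the
plane perpendicular to the **anatomical femoral axis**, with antetorsion
(neck pointing anteriorly) positive on both sides.

The three axes are constructed from a proximal and a distal femur segment —
the two regions a clinical torsion protocol actually scans — expressed in an
LPS patient frame (x left, y posterior, z superior, the DICOM frame of a
supine scan) in millimetres:

* **Neck axis.** The femoral head center comes from a least-squares sphere
  fit to a surface patch on the head; the other end is the area centroid of
  the narrowest neck cross-section. On clinical software the narrowest-neck
  plane is fitted by hand; `femtor` replaces that step with a deterministic
  search (below) and also accepts a user-supplied plane.
* **Condylar tangent.** The most posterior vertex of the medial and of the
  lateral condylar region, joined into a line oriented medial→lateral.
  "Most posterior" is evaluated inside user-declared regions rather than
  globally, because on a full distal femur the global posterior extreme can
  fall on either condyle; regions make the choice deterministic (ties break
  to the lowest vertex index). The posterior plane through both condylar
  points and the most posterior greater-trochanter point is computed and
  stored for audit, but the tangent that enters the angle is the two-condyle
  line.
* **Anatomical axis.** The line through the centroids of two *axial*
  (constant-z) shaft cross-sections: proximally at the level midway between
  the tips of the lesser and greater trochanter, distally just above the
  condylar region. "Axial" deliberately means scanner-axial rather than
  perpendicular-to-the-axis: the axis is *derived from* these sections, so
  defining the sections perpendicular to it would be circular.

### Sign convention and projection

Both the neck axis and the condylar tangent are treated as *lines*: after
projection onto the plane perpendicular to the anatomical axis, the angle is
taken between the neck projection and the medial sense of the condylar line
and folded into (−90°, 90°]. The rotation sense about the anatomical axis is
mirrored between sides so that anterior rotation of the neck is positive for
left and right femurs alike; retrotorsion is negative. Folding to line
semantics keeps the three defining constructions consistent: a neck parallel
to the condylar medial sense measures 0°, a neck tilted anteriorly to
perpendicular measures +90°, and a neck constructed by rotating the condylar
tangent anteriorly by θ about the anatomical axis measures exactly θ.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `scan_step` | 0.5 mm | plane spacing of the neck scan |
| `centroid_tol` | 0.1 mm | convergence of the neck-axis re-estimation |
| `max_iter` | 10 | cap on re-estimation passes |
| `distal_offset` | 10 mm | distal axial level above the condylar top (unspecified in clinical descriptions; exposed) |
| `region_radius` | 16 mm | radius of the condylar/trochanteric landmark regions |
| `axial_dir`, `posterior_dir` | +z, +y | frame axes; override only for rigidly transformed scenes |

The neck search starts from the corridor direction, scans planes
perpendicular to the current axis estimate at `scan_step`, keeps the
minimum-area section — using the section loop that encloses the corridor
point, so that the infinite plane slicing the trochanter or head elsewhere
cannot hijack the minimum — then re-estimates the axis from the head center
to the current centroid and rescans until the centroid moves less than
`centroid_tol` or `max_iter` is reached.

## Numerical choices

* **Sphere fit**: algebraic linear least squares provides the seed;
  Gauss–Newton on the geometric residual Σ(|p−c|−r)² refines it. Inputs with
  a near-singular centered covariance (coplanar points) are rejected.
* **Cross-sections** are exact triangle–plane intersections chained into
  closed loops through shared mesh edges. Chaining is undirected (each
  crossed mesh edge joins exactly two segments on a watertight mesh) and the
  loop orientation is decided by a majority vote of per-triangle traversal
  directions, which is robust when individual triangles lie almost parallel
  to the cutting plane. Loop areas are signed about the plane normal, so
  holes subtract from the enclosed area and the centroid; neck and shaft
  constructions use the main (largest-area) loop. On-plane vertices are
  nudged by 10⁻¹² mm to avoid degenerate intersections.
* **Extreme points** break ties by the smallest vertex index.
* **Angles** are computed with `atan2`; projections shorter than 10⁻⁹ are a
  degeneracy error (axis parallel to the anatomical axis).

## The synthetic femur

The generator builds a femur-like solid as the smooth union (quadratic
smooth-min, 3 mm blend) of signed-distance primitives: a shaft capsule along
z; a neck capsule tilted by the neck–shaft angle (default 128°) and rotated
about the shaft axis by the requested torsion θ, anterior positive; a head
sphere (default radius 24 mm) at the neck's end; two posterior condylar
ellipsoids whose posterior apices sit at equal posterior coordinate, making
their common tangent the exact 0° reference; and greater/lesser trochanter
bumps. The isosurface is extracted by marching tetrahedra over a regular
grid (default pitch 1.0 mm), which guarantees a watertight, consistently
oriented mesh — the reason for choosing an SDF isosurface over boolean mesh
unions, which are fragile at the junctions. The solid is cut into proximal
and distal segments mirroring the clinical scan coverage, and optional
Gaussian vertex jitter (seeded) emulates the coarser surface quality of
MRI-based segmentations. Default dimensions (neck radius 14 mm, shaft radius
15 mm, condyle semi-axes 18×27×24 mm at ±23 mm from the midline) are
adult-femur magnitudes.

Because the condylar reference and the neck rotation are exact by
construction, the generator's θ is ground truth rather than an estimate, and
the ground-truth record (head sphere, neck corridor, apices, trochanter
tips) is sufficient to run the full measurement with no manual input —
`params_from_ground_truth()` stands in for the interactive reader.

What the generator does *not* emulate: real anatomical shape variation
(it is a single parametric phantom, not a statistical shape model), cortical
thickness or interior structure, segmentation artefacts other than isotropic
vertex noise, and inter-reader variability in landmark selection. Passing
the synthetic recovery tests therefore demonstrates correctness of the
geometry pipeline under known truth, not clinical accuracy on patient
anatomy.

### Validation results the tests compute

* Torsion recovery over θ ∈ {−20°, …, +30°} at pitch 1.0 mm: within 1.0° at
  zero noise and 2.5° at 0.5 mm vertex noise — the noisy bound is of the
  same order as the ≈2° inter-modality SEM reported for the clinical
  measurement.
* Rigid-motion and mirror invariance within 0.1°, uniform-scale invariance
  within 10⁻⁶°, with landmarks and frame axes transformed alongside the
  meshes (a rigid transform moves "axial" and "posterior" with the scene;
  `MeasurementParams` carries those axes for exactly this reason).
* Sphere fit: exact recovery on noiseless samples (10⁻⁶ mm) and agreement
  with a grid-search oracle within 0.02 mm on noisy patches.
* Cross-sections against closed forms (cube, cylinder) and against a
  voxelized-SDF centroid oracle on the femur neck (0.25 mm sampling,
  0.5 mm agreement).

## The measurement-table simulator

`simulate_measurement_table()` draws a two-reader × two-modality table from
the additive model y = μ + sᵢ + δ·1[MRI] + rᵢⱼ + e with subject effects
sᵢ ~ N(0, σ_s²), reader-within-subject effects rᵢⱼ shared across modalities,
residual e ~ N(0, σ_e²) and an MRI bias δ, plus independent cell
missingness. With no modality bias (δ = 0) the within-reader inter-modality
ICC(A,1) has the closed form (σ_s² + σ_r²)/(σ_s² + σ_r² + σ_e²), which the
tests verify at σ_s = 9, σ_r = 0, σ_e = 2: 81/85 ≈ 0.953; a non-zero δ
additionally depresses absolute agreement through the rater mean square. Defaults (σ_s = 9°, σ_e = 2°) match the
dispersion and error scale of the packaged clinical table.

## The packaged study table

The packaged fixture is the published table of 3D torsion measurements:
15 subjects, right and left hips, two readers, CT and MRI — 120 cells of
which 118 carry values. Obvious typesetting artefacts of the printed table
("16. 2", "20. 6", a typographic minus) are normalized in the CSV, which is
checksum-verified on load. One hip (subject 2, left) has CT values but no
MRI; the published analysis cohort is the 29 hips with complete data, and
`reproduce_paper_results()` therefore runs the report with
complete-case-across-all-columns deletion (`listwise = "across_all"`), the
behaviour of running one analysis dataset through SPSS. With per-comparison
listwise deletion instead, the CT inter-reader comparison would keep that
30th hip (n = 30) and its ICC/SEM would shift to 0.955/1.90 — outside the
reproduction tolerance of the printed 0.957/1.83, which is how the cohort
choice was settled. Both modes are exposed on `build_report()`.

Reproduction tolerances are 0.005 for ICCs and 0.05° for degree-valued
summaries: the packaged values are rounded to 0.1°, so agreement with the
original unrounded analysis beyond that cannot be expected; deviations
beyond tolerance are printed, never suppressed. The study's per-reader
"intra-observer variability" values (1.51/1.62) are reported without a
defined metric; the report computes and labels the per-reader mean signed
and mean absolute CT–MRI differences (`per_reader`), neither of which
matches those numbers, and makes no claim to reproduce them.

## ICC machinery

ICC(A,1) is computed from the two-way ANOVA mean squares (units × raters,
one observation per cell), with the F-based confidence interval using
Satterthwaite degrees of freedom. The "two-way random" (inter-reader) and
"two-way mixed" (inter-modality) designs share the same absolute-agreement
single-measures estimator; the tag is recorded because the interpretation —
generalising to a population of readers vs to these two fixed modalities —
differs, not the arithmetic. Zero-variance inputs raise a typed
undefined-ICC error rather than returning NaN. SEM uses the sample standard
deviation of *all* measurements entering a comparison (both columns
stacked); this convention back-solves to the published SEMs given the
published ICCs, and is documented here so it can be revisited against other
conventions (e.g. pooled within-subject sd).

## Problem sizes and limitations

The validation suite runs synthetic femurs at 1.0–1.8 mm pitch (10⁵-vertex
meshes), sphere oracles on 100-point patches, and simulated tables of
500–2500 subjects; these sizes make the full suite complete in a few
minutes while keeping Monte-Carlo error well inside the asserted
tolerances. Known limitations: no DICOM ingestion or segmentation (surface
models are the input), no automatic anatomical region detection (head
patch, neck corridor, condylar regions and trochanter tips are user inputs,
by design mirroring the interactive clinical workflow), a single LPS frame
convention, and binary STL's float32 storage (use ASCII STL or PLY when
1e-6 mm round-trips matter).
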
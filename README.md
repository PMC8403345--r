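# femtor — 3D femoral torsion from bone surface models

Femoral torsion (antetorsion) is the axial-plane angle between the femoral
neck axis and the posterior condylar tangent. Aberrant torsion is associated
with femoroacetabular impingement, hip dysplasia and early osteoarthritis,
and its diagnostic workup relies on CT or MRI. Two-dimensional slice methods
struggle with the femur's three-dimensional shape, so modern practice
measures torsion directly on 3D bone models segmented from the scans.

`femtor` implements this 3D measurement as a deterministic, testable
pipeline on triangulated surface meshes, together with the agreement
statistics used to validate such measurements across readers and imaging
modalities, and a synthetic femur generator with known ground-truth torsion
for end-to-end validation without patient data.

## The measurement

Given a proximal and a distal femur segment (STL or PLY, millimetres, LPS
patient frame: x left, y posterior, z superior):

1. **Femoral head center** — least-squares sphere fit (algebraic seed +
   Gauss–Newton refinement) to a user-selected surface patch on the head.
2. **Neck isthmus** — planes perpendicular to the running neck-axis estimate
   are scanned along a corridor bracketing the neck; the minimum-area
   cross-section is kept and the axis re-estimated (head center → section
   centroid) until the centroid stabilises below 0.1 mm.
3. **Femoral neck axis** — the line from the isthmus centroid to the head
   center.
4. **Posterior condylar tangent** — the line through the most posterior
   points of the medial and lateral condyles (selected within user-declared
   regions; the posterior plane through both condyles and the greater
   trochanter is recorded for audit but does not enter the angle).
5. **Anatomical femoral axis** — through the centroids of two axial shaft
   cross-sections: at the level midway between the trochanter tips, and just
   above the condyles (default 10 mm).
6. **Torsion** — neck axis and condylar tangent are projected onto the plane
   perpendicular to the anatomical axis; the signed angle between the
   projections is reported with antetorsion positive on both sides (the
   rotation sense is mirrored for right femurs).

Reliability statistics follow the standard agreement-study toolkit:
ICC(A,1) — two-way ANOVA, absolute agreement, single measures,

    ICC(A,1) = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE)),

with F-based 95% confidence intervals, SEM = sd·√(1 − ICC), and the paired
t-test on pooled MRI − CT differences.

## Worked example

```r
library(femtor)

# a synthetic right femur with 15 degrees of true antetorsion
fem    <- generate_femur(femur_params(theta = 15, side = "right", pitch = 1.0))
params <- params_from_ground_truth(fem$truth, fem$proximal)
meas   <- measure_torsion(fem$proximal, fem$distal, params)
meas
#> <torsion measurement> right femur: 14.96 deg (antetorsion positive)
#>   head center (45.67, -12.24, 441.94) mm, radius 24.00 mm (rms 0.003 mm)
#>   neck isthmus area 615.3 mm^2, centroid (24.36, -6.53, 424.70) mm
```

The measured 14.96° recovers the generator's 15° within the surface
discretization error; the head sphere lands on the true center to a few
hundredths of a millimetre, and the isthmus area matches the generator's
14 mm neck radius (π·14² ≈ 615.8 mm²). `tidy(meas)` returns the same record
as a one-row tibble, `autoplot(meas)` draws the axial projection in which
the angle is defined, and `write_torsion_json()` dumps every intermediate
landmark.

The packaged two-reader, two-modality study (29 hips with complete CT and
MRI measurements) is recomputed with:

```r
reproduce_paper_results()
#> <reliability report> 29 hips (across-all deletion)
#>   inter_modality reader 1  ICC(A,1) 0.951 (0.899; 0.976)  SEM 1.96 deg  n = 29
#>   inter_modality reader 2  ICC(A,1) 0.951 (0.898; 0.976)  SEM 1.92 deg  n = 29
#>   inter_reader   CT        ICC(A,1) 0.957 (0.909; 0.979)  SEM 1.84 deg  n = 29
#>   inter_reader   MRI       ICC(A,1) 0.945 (0.887; 0.974)  SEM 2.02 deg  n = 29
#>   MRI - CT pooled: mean 0.42 deg (SD 2.76), t(57) = 1.17, p = 0.248, n = 58 pairs
#>   observed range: -16.4 to 28.2 deg
#> reproduction: 12/12 printed values within tolerance
```

The inter-modality ICCs near 0.95 say that CT- and MRI-based 3D torsion
measurements agree to within about 2° of expected measurement error (the
SEM), i.e. MRI-based models are a usable radiation-free alternative for
this measurement; the inter-reader ICCs say two trained readers reproduce
each other to similar precision.

A command-line interface wraps the same functions
(`inst/cli/femtor measure | simulate-femur | simulate-table | reliability`);
see `Rscript inst/cli/femtor --help`.

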
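Package: femtor
Title: Three-Dimensional Femoral Torsion Measurement from Bone Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures femoral torsion (antetorsion) in three dimensions from
    triangulated surface models of the proximal and distal femur: least-squares
    sphere fit to the femoral head, minimum-area cross-section at the femoral
    neck isthmus, posterior condylar tangent, anatomical femoral axis from
    axial shaft cross-sections, and the signed angle between the neck axis and
    the condylar tangent projected onto the plane perpendicular to the
    anatomical axis. Includes a synthetic femur generator with known
    ground-truth torsion for validation, simulation of reader/modality
    measurement tables, and the reliability statistics used in agreement
    studies: intraclass correlation coefficients (two-way ANOVA, absolute
    agreement, single measures) with 95% confidence intervals, standard error
    of measurement, and paired comparisons. Ships a published 29-hip CT/MRI
    inter-reader dataset as a fixture together with a harness that recomputes
    its reliability results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    withr,
    optparse,
    rlang
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
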
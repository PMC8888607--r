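Package: myoline
Title: Volumetric Muscle Geometry: Attachment Centroids, Lines of Action, and Mass Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for musculoskeletal modelling from closed polygonal muscle
    meshes: area-weighted attachment-area centroids via Heron-formula
    triangle areas, automated muscle line-of-action (LoA) estimation by
    slicing a muscle mesh along the origin-insertion axis and threading
    the area-weighted cross-section centroids into a path, closed-mesh
    volume and muscle mass estimation at standard tissue densities
    (muscle 1060 kg/m3, tendon 1120 kg/m3), and an agreement-statistics
    layer (Bland-Altman, Mann-Whitney U, within-range summaries, linear
    regression comparisons) for evaluating mass estimates against
    dissection measurements. Includes a synthetic muscle-mesh generator
    (tubes with known centerlines, primitives, oblique-capped prisms)
    providing analytic ground truth for every geometric operation, and
    exporters for musculoskeletal simulation software (OpenSim path
    points, OBJ polylines, CSV, JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
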
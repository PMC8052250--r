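Package: vesselpath
Title: Curvature-Constrained Path Planning Along Vascular Centerlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase path planning for catheter-like flexible devices
    navigating tubular anatomy. A global breadth-first search over a
    k-nearest-neighbour graph of vascular centerline points produces a
    tentative cubic B-spline curve; a genetic-algorithm local optimizer
    then re-fits exactly those curve segments whose curvature exceeds the
    device's bending capability, trading off wall clearance, curvature and
    path length under a penalty-method cost. Includes centerline readers
    and writers (VTK PolyData, CSV, JSON), a synthetic vascular-tree
    generator with tortuosity-calibrated presets, centerline-sampling RRT
    and RRT* baselines, and a benchmarking harness with rank-based
    statistical comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    splines,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
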
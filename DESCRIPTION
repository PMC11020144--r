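Package: rootpose
Title: Landmark-Based Root System Architecture Trait Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation-free root phenotyping from landmark (pose) data.
    Roots detected as ordered polylines of named nodes across multi-view image
    series are turned into whole root-system architecture trait suites: a
    dicot pipeline (primary + lateral roots, 35 per-frame traits, 1,035
    summarized traits per plant) and a younger-monocot pipeline (primary +
    crown roots, 30 per-frame traits, 918 traits per plant). Traits are
    organized in a dependency graph and evaluated per frame in topological
    order, then aggregated with nine summary statistics at frame and plant
    level. Includes per-root geometry operators (lengths, gravity angles,
    curve index, root-width estimation by Hungarian matching of left/right
    lateral bases), frame-level morphometrics (convex hull, least-squares
    ellipse fit, horizontal scanline intersection profiles, network length
    and solidity), a parametric synthetic root-system generator with known
    ground truth, and statistics to compare trait tables from proofread
    versus automated landmark sets (z-score differences and per-trait
    Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
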
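Package: vasctree
Title: Topology, Morphometry and Scaling Analysis of Whole-Organ Vascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-organ arterial networks represented as
    spatial graphs (centreline skeletons with per-point radii). Reads and writes
    AmiraMesh ASCII spatial graphs and a tabular dialect, validates and roots
    vessel trees, assigns truncated Strahler orders and topological generations,
    fits branching ratios, corrects skeleton artifacts (centreline smoothing,
    collapsed-vessel flagging and perimeter-based radius correction from binary
    volumes), computes branching morphometry (tortuosity, branching angles,
    length to diameter ratio, inter-vessel distance, compartment assignment),
    fits radial scaling exponents by standard major axis regression against
    Murray's law and the West-Brown-Enquist model, and validates skeletons
    against segmentations (clDICE topological precision and recall, a
    five-component skeleton super-metric). Includes a seeded synthetic
    vascular-tree and phantom-volume generator so every stage is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
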
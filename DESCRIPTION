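Package: linkpeak
Title: Pseudomolecule Construction from Genetic Maps and Mate-Pair Link Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ordering and orienting an unordered scaffold assembly
    into chromosome-scale pseudomolecules.  Anchors sequence-tagged-site
    markers to scaffolds through a repeat-depth and mate-consistency filter
    cascade, adds in silico anchors from clone ends, whole-genome-profiling
    tags and synteny with a related genome, scores windowed mate-pair
    "link peaks" with a noise score to call reciprocal scaffolding links,
    detects and splits chimeric scaffolds, and emits AGP 2.0 layouts,
    wiggle evidence tracks and assembly statistics.  Includes genetic-map
    quality control (missing-data filtering, co-segregation collapse,
    segregation-distortion scans, Kosambi conversion), Marey-map
    recombination profiling with pericentromere boundary calling, and a
    seeded synthetic-data generator with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    stats,
    utils,
    generics,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
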
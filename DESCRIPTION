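Package: phytoarray
Title: Focused Two-Color Array Analysis of Anti-Inflammatory Phytocompounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for comparative functional genomics of
    anti-inflammatory phytocompounds in LPS-stimulated monocytes assayed on
    focused two-color (Cy3/Cy5) DNA microarrays. Processes per-hybridization
    spot tables into housekeeping-normalized expression ratio matrices,
    applies the 3-fold differential filter, classifies treatment-vs-LPS
    time profiles into kinetic regulation modes and scores between-treatment
    mode concordance, clusters profiles by UPGMA with Newick export, and
    searches signed directed signaling networks for bounded-depth upstream
    master regulators (key nodes) with activation/inhibition sign
    propagation. Includes seeded simulators for spike-in spot tables and
    planted-regulator networks, and packaged fixtures of the published
    ratio tables.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
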
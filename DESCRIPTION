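Package: achrotools
Title: Carbonate Chemistry, Calcite-Driven Energetics, and Single-Cell
    Genome QC for Achromatium Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative models for calcite-precipitating, sulfur-oxidizing
    Achromatium bacteria in brackish spring systems. Implements
    carbonate-system speciation from pH and bicarbonate (with calcite
    saturation state), the proton and ATP yield of intracellular calcite
    precipitation via vacuolar proton pumps, division-capacity accounting for
    ATP budgets, sediment reservoir budgets of dissolved versus acid-volatile
    sulfide, single-cell genome quality metrics (contig filtering, N50, GC
    unimodality, marker-gene completeness, genome-size extrapolation), 16S
    rRNA phylotype identity and helix-38 cluster assignment, and seeded
    synthetic-data generators with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
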
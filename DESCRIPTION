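Package: pcgcoloc
Title: Comparative ChIP-Seq Occupancy Analysis at Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for comparing Polycomb-group (PcG) protein
    occupancy between genotypes at transcription factor binding sites from
    ChIP-seq tag data. Provides IgG-normalized average signal profiles and
    per-peak heat-map matrices anchored at peaks, TSS-distance-matched random
    control regions, 1.5-fold ratiometric gain/loss classification with
    chi-squared enrichment tests, CpG-island proximity stratification,
    observed/expected peak co-occurrence matrices around TSS and transcription
    ends, and the companion microarray fold-change/t-test filtering. Includes a
    synthetic-data generator that plants binding-site classes with known
    occupancy changes so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
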
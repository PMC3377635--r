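Package: coraldive
Title: Barcode Diversity and Bathymetric Profiling for Deep-Sea Octocorals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multi-marker DNA-barcode and biogeographic analysis of
    deep-sea octocorals (Calcaxonia). Computes alignment information content
    (variable and parsimony-informative sites), collapses aligned sequences
    into haplotypes and tabulates richness by ocean basin, computes pairwise
    uncorrected p-distances with transition/transversion tallies and applies a
    distance-threshold family-delimitation rule, and curates depth records
    from mixed point and trawl stations to build species depth ranges and
    100-m species-diversity profiles. Includes seeded simulators for sequence
    alignments evolving on birth trees and for occurrence records with known
    ground truth, so every pipeline stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
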
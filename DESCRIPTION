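Package: shrnaoff
Title: Quantifying Sequence-Specific Off-Target shRNA Effects on Promoter Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the quantitative workflow used to
    characterize shRNA effects on promoter reporters that are sequence-specific
    but independent of the intended gene target. Provides spike-in-calibrated
    normalization of hybridization-based miRNA counts (Ei = (Ri - B)/slope with
    global mean rescaling), paired differential-expression calling with signed
    linear fold-change thresholds, reporter-assay scoring (relative luciferase
    activity, flow-cytometry percent-positive x median composite scores,
    delta-delta-Ct qPCR quantification), structural parsing of pLKO.1-style
    shRNA hairpin oligos, and integration of differential-expression sets with
    miRNA-target maps and gene-family enrichment. A synthetic-data module
    generates every input with known planted effects so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
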
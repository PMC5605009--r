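Package: synthct
Title: Synthetic CT Generation from Multi-Sequence MRI and Image-Similarity Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates bulk-density-assigned synthetic CT (BCT) and
    water-equivalent CT (WCT) volumes from co-registered T1-weighted,
    T2-weighted and PETRA MR images of the head, using rule-based intensity
    classification with atlas-style locational priors for eight intracranial
    anatomies, and evaluates the result against a reference CT with Dice
    overlap coefficients (DSC, FND, FPD), four histogram-similarity measures
    (correlation, chi-square, intersection, Bhattacharyya distance) and a
    gamma-index analysis on CT numbers with distance-to-agreement search.
    Includes a digital head-phantom simulator producing grid-aligned label
    maps, MR sequences and a reference CT, so the full pipeline can be
    exercised end to end, plus Welch two-sample testing and power-based
    sample-size verification for cohort studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
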
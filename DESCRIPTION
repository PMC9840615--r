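Package: numerosity
Title: Dot-Array Numerosity Stimuli: Generation, Property Extraction and
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-alternative numerosity-comparison experiments with
    dot-array stimuli. Generates area-controlled dot-array stimulus sets in
    five classic designs (side-by-side pairs, sequential pairs, and two-color
    intermixed arrays), renders them to raster images, and extracts numerical
    and visual properties from the images: dot ratio; total, mean and standard
    deviation of dot areas, perimeters and pairwise centroid distances; convex
    hull area and two hull-based density indices; and three 64-bit perceptual
    image hashes (average, DCT and Haar-wavelet) compared by Hamming distance.
    A Weber-law behavioral simulator produces trial-level data so the full
    analysis chain is testable end to end: participant-level outlier
    exclusion, per-stimulus aggregation of error rate and correct-trial
    reaction time, property-ratio correlations, per-property explained
    variance on behavior, and hierarchical incremental R-squared of dot ratio
    controlling each visual property, with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    EBImage,
    pheatmap,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
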
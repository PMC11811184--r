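Package: regiontune
Title: Region-Based Feature Coding Analysis for Single-Neuron Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and characterization of region-based feature coding in
    single neurons recorded while subjects view natural object stimuli. Builds
    2D stimulus feature spaces, detects significant tuning regions with
    Gaussian-smoothed density maps and permutation cluster statistics,
    classifies category-selective neurons (single-category versus
    multiple-category, feature versus non-feature), tests axis-coding models
    with cross-validated partial least squares regression, decodes object
    category from pseudo-populations with a maximum-correlation classifier,
    and links tuning regions to recognition-memory performance and image
    memorability. Includes a synthetic-data generator with planted ground
    truth so the full pipeline is testable end to end.
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
    mixOmics,
    withr
Config/testthat/edition: 3
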
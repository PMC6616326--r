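Package: phenoscan
Title: Image-Based Seedling Phenotyping and QTL Interval Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for image-based seedling vigor
    phenotyping and downstream genetic analysis. Converts RGB plant
    images to HSI and CIELAB color spaces, rescales the hue, a* and b*
    channels to a common 0-255 range, segments green seedling tissue by
    multi-channel thresholding followed by median denoising,
    morphological opening and hole filling, and extracts projected plant
    height and projected pixel area from the binary mask. Downstream
    tools compute per-line least-square means, Pearson correlations
    among traits and a residual-variance F test, and map quantitative
    trait loci on recombinant inbred line populations by Haley-Knott
    regression interval mapping with genome-wide permutation thresholds.
    Includes generators for synthetic seedling scenes with per-pixel
    ground truth and simulated RIL populations with planted QTL so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    farver,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
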
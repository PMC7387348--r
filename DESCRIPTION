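Package: sccount
Title: Automated Counting of Dark Circular Cells in Brightfield Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts darkly stained, round, cFos-like immunoreactive cells in
    brightfield brain-tissue images. The pipeline converts images to 8-bit
    grayscale, applies a global intensity threshold, removes noise with
    adaptive morphological opening (iterations driven by the threshold to
    mean-pixel-intensity ratio), selects objects by area and by circularity
    scored with the log-adjusted first Hu moment, and resolves fused
    overlapping cells with a small convolutional classifier trained on
    synthetic binarized patches. Ships a fabricated-image generator with
    exact ground truth, error-analysis metrics (absolute error, detection
    matching, count regression), and resize/threshold sweep utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
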
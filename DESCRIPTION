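Package: pillchroma
Title: Imaging-Condition Robustness Analysis for Pill Colour and Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how background colour, camera flash and exposure value
    affect the apparent colour of solid oral medications and the accuracy of a
    pill classifier. Provides a synthetic pill-image generator with ground-truth
    masks for a 2x2x3 factorial grid of imaging conditions plus a reference
    condition, a nine-step region-of-interest extraction pipeline (grayscale,
    blur, threshold, Canny edge tracing, contour fill, mask and square crop),
    CIE L*a*b* colorimetry with Euclidean colour difference (Delta E), a
    nearest-class-mean surrogate classifier with top-k accuracy evaluation per
    condition, and repeated-measures ANOVA of the colour differences with
    Bonferroni-adjusted exposure-value contrasts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
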
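Package: nestscan
Title: Pigeon Egg Detection and Barcode-Based Cage Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pigeon-egg inspection system for caged squab
    farming. Implements the numeric cores of a lightweight egg detector
    (the SimAM parameter-free attention energy function and the WIoU-v3
    dynamic non-monotonic focusing loss), temporal majority-voting fusion
    of repeated nest observations with its binomial reliability model, and
    a complete EAN-13 barcode pipeline (grayscale conversion, median
    filtering, Otsu thresholding, Canny edge detection, contour screening
    and from-scratch decoding) that turns a cage label into a validated
    8-digit house/cage/group/nest position code. A seeded synthetic scene
    generator emulates 1920x1080 cage frames with egg ellipses, wire-grid
    occluders, a rendered barcode label, impulse noise and transient
    occlusion, so the full "position-quantity" record-keeping loop runs
    end to end without farm hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
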
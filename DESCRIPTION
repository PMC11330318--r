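Package: circulus
Title: Automated Detection of Fish Scale Growth Rings Along Radial Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting incremental growth information from images of
    teleost fish scales. The pipeline locates the scale focus, extracts radial
    transect strips at configurable angles pivoting on the focus centre,
    detects individual growth rings (circuli) along each transect, and derives
    inter-circuli distances and spacings. Includes reading and writing of
    Pascal-VOC bounding-box annotations, reproducible dataset splitting, a
    pluggable object-detector backend contract with classical reference
    detectors, a full detection-evaluation protocol (IOU matching, precision,
    recall, F1, all-point average precision, mean centre error,
    count-difference statistics), and a synthetic scale-image simulator with
    pixel-exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
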
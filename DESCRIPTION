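Package: handmetry
Title: Hand Anthropometry from Calibrated Photographs for Arthritis Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement engine for hand optical imaging: calibrates a
    photograph of a hand resting on a letter-size sheet of paper to
    millimetre coordinates (Hough-transform edge and corner detection of
    the paper, followed by a four-point projective calibration), segments
    the hand silhouette, locates fingertips and interdigital valleys,
    and measures finger lengths, joint thicknesses, segment angulation
    and interphalangeal angular deviation.  Longitudinal comparison of
    measurement records flags suspected joint swelling and deviation
    progression for rheumatoid arthritis self-monitoring.  Includes a
    parametric synthetic hand-scene renderer with exact ground truth
    used to validate every stage of the pipeline, plus a minimal
    self-management symptom log.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
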
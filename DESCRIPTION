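Package: fishstereo
Title: Refraction-Corrected Binocular Stereo Measurement of Fish Body Length
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-contact underwater fish body-length measurement from stereo
    keypoint detections. Corrects keypoint pixel coordinates for the
    water-glass-air secondary refraction introduced by a flat-port waterproof
    enclosure, triangulates the corrected keypoints by linear least squares,
    and computes body length and relative-error statistics. Includes Zhang's
    planar-target camera calibration, COCO-style keypoint annotation I/O,
    keypoint evaluation metrics (normalized mean error, average precision over
    IoU thresholds), and a synthetic refractive stereo-scene simulator that
    serves as a ground-truth oracle for the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
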
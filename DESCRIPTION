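Package: kneegait
Title: Mobile Inertial Gait Analysis for Knee Arthroplasty Outcome Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a three-sensor (pelvis, thigh, shank)
    inertial gait-analysis protocol used to measure functional outcome before
    and after knee arthroplasty. Covers quaternion orientation estimation from
    9-DoF streams, sensor-to-segment anatomical calibration from standing and
    flexed-knee captures, knee flexion angle and angular velocity from the
    thigh-shank relative orientation, gait event detection from the shank
    gyroscope, spatiotemporal parameters over annotated path lengths, stair and
    instrumented Timed-Up-and-Go metrics, knee stability and fatigue
    surrogates, and pre/post outcome statistics with clinical score banding and
    rank correlations. Includes a parametric gait simulator that synthesises
    full annotated 9-DoF sessions with ground truth so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
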
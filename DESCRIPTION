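Package: swingtrack
Title: Wrist Trajectory Reconstruction from a Single Wrist-Worn IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Reconstructs the three-dimensional wrist trajectory of a golf
    swing from a single wrist-worn inertial measurement unit (IMU).  The
    sensor-to-ground orientation at address is estimated with a small
    convolutional network (with a population-average quaternion baseline),
    orientation is propagated over the swing by first-order quaternion
    strapdown integration of the gyroscope, and integration drift is removed
    with two kinematic constraints: zero wrist speed at the address,
    backswing-top and finish events, and an endpoint constraint on a virtual
    circle fitted in the swing plane.  A physically consistent synthetic
    swing simulator with full ground truth makes the complete pipeline
    testable without recorded data.  Includes preprocessing (Butterworth
    low-pass filtering, range-clipping detection and spline repair),
    swing-phase segmentation with a bidirectional recurrent network,
    evaluation metrics, CSV input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
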
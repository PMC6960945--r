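Package: imujoint
Title: Magnetometer-Free 3D Joint Angle Estimation from Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the three-dimensional angle of a spherical (ball-and-socket)
    joint from the gyroscope and accelerometer signals of two body-worn inertial
    measurement units, without any magnetometer. A sequential direction-cosine-matrix
    Kalman filter first estimates each sensor's attitude (inclination) with a
    Gauss-Markov external-acceleration compensation mechanism, then estimates the
    heading of one link by strapdown gyroscope integration and corrects the heading
    of the other link using the acceleration-level kinematic constraint that both
    links share the joint-center acceleration. Because no magnetic reference is used,
    the joint angle is immune to magnetic disturbance. The package includes a
    kinematically consistent two-link and n-link chain motion simulator, least-squares
    identification of the sensor-to-joint-center vectors, joint-angle evaluation
    metrics, CSV/JSON interchange, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
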
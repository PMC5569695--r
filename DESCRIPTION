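Package: headkin
Title: Head Impact Kinematics, Brain Strain Reduction and Regression Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Laboratory-to-statistics pipeline for helmeted head impact
    experiments instrumented with a 3-2-2-2 nine-accelerometer array.
    Simulates rigid-body impact motion and the accelerometer channels it
    produces, reconstructs 6-DOF head kinematics about the centre of mass
    (Padgaonkar nine-accelerometer transform, SAE J211 channel-frequency-class
    phaseless filtering, trapezoidal integration to velocities), reduces the
    kinematic time series to thirteen scalar predictors, reduces finite-element
    style brain strain time-histories to the cumulative strain damage measure
    (CSDM-15) and maximum principal strain (MPS), and compares linear
    regression models of strain on kinematics via adjusted R-squared and the
    overall F-statistic across an enumerated model set, overall and per impact
    location.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
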
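Package: strideAR
Title: Stride-Time Pattern Stability Analysis via Second-Order Autoregressive Modeling
Version: 0.1.0
Authors@R:
    person("strideAR", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to assess the dynamic stability of gait stride-interval time
    series with second-order autoregressive (AR(2)) models. A stride-time series
    is linearly detrended, an AR(2) model is fitted, and the coefficient pair
    (phi1, phi2) is located on the AR(2) stationarity triangle; the Euclidean
    distance to the triangle centroid (0, -1/3) serves as a unitless stability
    statistic. Includes readers for the PhysioNet gaitndd columnar format and an
    internal CSV dialect, a synthetic gait-cohort generator for fully offline
    testing, group-level comparison (Welch and pooled t-tests, 95% coverage
    ellipses, distance-threshold classification), and a reproducible
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
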
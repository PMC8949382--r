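Package: patraj
Title: Latent Class Trajectory Profiles of Accelerometer-Measured Physical Activity
Version: 0.1.0
Authors@R: person("Sophia", "Lindqvist", email = "sophia.lindqvist@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying trajectory profiles of physical activity and
    sedentary behaviour from minute-epoch accelerometer data collected over
    repeated measurement waves. Implements wear-time and bout detection with
    counts-per-minute cut-points, compositional time-use features (isometric
    log-ratio pivot coordinates), latent class linear mixed models for
    multivariate longitudinal outcomes fitted by EM, fit-index based class
    enumeration, and logistic regression with backward elimination for
    baseline predictors of profile membership. Includes a seeded synthetic
    cohort generator with known two-class structure for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
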
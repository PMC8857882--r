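Package: imuRehab
Title: Movement-Quality Metrics from a Single Shank-Worn Inertial Sensor
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised evaluation of home-based physiotherapy exercise
    recordings captured with a single shank-worn inertial measurement unit
    (IMU). Segments exercise repetitions from the periodicity of the
    acceleration signal and computes movement-quality metrics: cycle
    duration, log dimensionless jerk (LDLJ) smoothness, movement intensity
    and its variability, range of angular velocity, a kinetic (work-done)
    value, autocorrelation-based movement regularity, and dynamic time
    warping (DTW) stability. Includes a synthetic-recording generator with
    ground truth for validation, batch processing over cohorts of
    recordings, lab-versus-home session summaries against demonstration
    paces, and a paired sign-flip permutation comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'dtw.R'
    'imu-io.R'
    'imuRehab-package.R'
    'methods.R'
    'metrics-filter.R'
    'segmentation.R'
    'metrics.R'
    'synthetic.R'
    'reporting.R'
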
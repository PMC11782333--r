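Package: avfsound
Title: Acoustic and Hemodynamic Analysis of Arteriovenous Fistulae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links the sound of a hemodialysis arteriovenous fistula (AVF)
    to its hemodynamics. Implements the high-low peak ratio (HLPR), a
    spectral statistic of stethoscope recordings (ratio of the maximum FFT
    amplitude in the 500-700 Hz band to that in the 100-250 Hz band after
    trimming and 4th-order Butterworth high-pass filtering at 50 Hz);
    post-processing of wall-shear-stress fields into oscillatory shear
    index (OSI) maps, threshold-area fractions and cross-sectional-area
    profiles along a centerline; Doppler-ultrasound blood flow volumes;
    and the cohort statistics tying them together (median-split subgroup
    comparison, random-intercept mixed models with cluster-bootstrap
    confidence intervals, longitudinal deltas, operator agreement).
    Synthetic-data generators for phonoangiograms, pulsatile shear fields
    and longitudinal cohorts make every stage testable without patient
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
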
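Package: microbrachy
Title: Treatment Planning, Voxel Dosimetry and Survival Analysis for
    Ho-166 Microbrachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computational pipeline for intratumoral Ho-166
    microparticle brachytherapy of small brain tumors: synthetic plurilobed
    tumor phantoms and contrast-CT volumes, an exponential tumor growth
    model, a physical model of the radioactive microparticle suspension
    (decay kinetics, cumulated activity, unit-of-treatment mass and
    activity), a dose-point-kernel voxel dose engine with a brute-force
    oracle, a fewest-injections greedy treatment planner targeting 95
    percent of 100 Gy over 95 percent of the gross tumor volume, CT
    Hounsfield-unit calibration and holmium quantification, dose-volume
    histogram coverage metrics, and a first-principles Kaplan-Meier /
    Mantel-Cox log-rank survival comparison for two-arm animal cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
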
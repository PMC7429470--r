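Package: mbdwi
Title: Multi-b-Value Diffusion MRI Models and Treatment-Response Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the three classical signal-decay models of multi-b-value
    diffusion-weighted MRI (mono-exponential ADC, segmented bi-exponential
    intravoxel incoherent motion, and stretched-exponential DDC/alpha) to
    voxel- or region-level data, simulates Rician-noise DWI phantoms and
    two-group two-time-point patient cohorts, aggregates tumor-ROI
    parameters over the three maximal consecutive slices, classifies
    treatment response with RECIST v1.1 diameter rules, and runs the
    associated biostatistics: normality-routed two-group comparisons,
    chi-square tests, interobserver intraclass correlation, and ROC
    analysis with Youden-index cutoffs and predictive values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    minpack.lm,
    nortest,
    pROC,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
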
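Package: spherosed
Title: Biophysical Characterization of 3D Cell Spheroids by Sedimentation
    Velocimetry and Cleared-Sample 3D Nuclei Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the mass density, mass, buoyant weight and diameter of
    3D cell spheroids from the terminal velocity they reach while settling
    in a quiescent vertical fluid channel (Stokes sedimentation
    velocimetry), including bright-field video tracking, velocity fitting
    and quality control. Also provides the accompanying cohort statistics
    pipeline (Shapiro-Wilk normality gating, Tukey-fence outlier removal,
    Student t-tests, dose-response Pearson correlation, fixation-effect
    one-way ANOVA, fluorescence standard-curve calibration) and a 3D
    nuclei quantification pipeline for cleared-spheroid confocal stacks
    (Richardson-Lucy deconvolution, z-alignment, Laplacian-of-Gaussian
    spot detection, seeded watershed growth, morphological label cleanup,
    nuclei counting, spheroid volume, volumetric nuclear density and
    bright-field optical density). Seeded synthetic-data generators with
    known ground truth cover every input kind for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
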
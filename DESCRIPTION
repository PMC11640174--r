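Package: tenchaHSI
Title: Hyperspectral Calibration of Total Free Amino Acids Across Tea
    Processing Steps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Visible/near-infrared hyperspectral calibration of total free
    amino acid (TFAA) content in Tencha tea leaves across processing steps
    (fresh-leaf spreading, steaming fixation, hot-air drying). Provides
    reflectance calibration of raw cubes against white and dark reference
    frames, ENVI-format input/output, ninhydrin-assay standard-curve
    chemistry, spectral pretreatments (multiplicative scatter correction,
    mean centring, Savitzky-Golay smoothing and first derivative), SPXY
    sample-set partitioning on joint X-Y distances, CARS and VISSA
    wavelength selection with RMSECV trajectories, partial least squares
    regression and least squares support vector regression with
    cross-validated tuning, RPD-based model evaluation tables, pixel-wise
    concentration mapping, and a seedable synthetic-data generator that
    emulates the study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    signal,
    jsonlite,
    yaml,
    png,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
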
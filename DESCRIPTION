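Package: teaspec
Title: Hyperspectral Chemometrics for Black Tea Fermentation Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative prediction and spatial mapping of catechin
    content in fermenting black tea from visible/near-infrared hyperspectral
    images. Includes a fermentation-structured synthetic data generator with
    known first-order catechin decay kinetics, reflectance calibration and the
    standard spectral pretreatments (Savitzky-Golay smoothing and second
    derivative, SNV, MSC, centering, z-score and min-max standardization),
    Kennard-Stone sample partitioning, characteristic-wavelength selection by
    the successive projections algorithm, the shuffled frog leaping algorithm
    and variable combination population analysis with genetic-algorithm or
    IRIV refinement, PCA score compression, PLS/ELM/SVR calibration models
    evaluated by Rc/RMSECV/Rp/RMSEP/RPD, and pixel-wise concentration maps
    with background masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    e1071,
    yaml,
    jsonlite,
    png,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
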
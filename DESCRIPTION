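Package: brachydeck
Title: DICOM RT Parsing and Monte Carlo Input Deck Generation for HDR
    Brachytherapy Dosimetry QA
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quality assurance of high-dose-rate Ir-192
    brachytherapy dose calculation. Reads and writes the four DICOM RT
    information objects used in brachytherapy planning (CT image series,
    RT Plan, RT Structure Set, RT Dose), converts a CT volume into a
    voxelized material model (Hounsfield-unit to density calibration,
    density binning, tissue composition lookup), emits an MCNP-style
    Monte Carlo input deck with a phase-space source representation and
    per-dwell rigid transforms, renders reference dose grids with a TG43
    line-source engine, and provides the benchmarking computations used
    to compare dose grids: percentage-difference maps and histograms,
    radial dose function and 2D anisotropy function extraction,
    dose-volume histograms, and morphological skin derivation. Synthetic
    phantom generators (water sphere in air, multicatheter plans) make
    the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
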
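Package: mrlqa
Title: Quality Assurance Analysis for the MRI Component of an MR-Linac
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for routine image quality assurance of a 1.5 T MR-linac:
    periodic image-quality metrics (signal-to-noise ratio, uniformity,
    spatial linearity, slice profile, pixel size, central frequency),
    three-dimensional geometric distortion from a fiducial-grid phantom
    summarized per diameter of spherical volume, gantry-angle-resolved B0
    and B1 field mapping from dual-echo and dual-TR acquisitions,
    quantitative T1 (variable flip angle), T2 (multi-echo spin echo) and
    apparent diffusion coefficient mapping with bias and reproducibility
    statistics, and longitudinal tolerance/trend reporting. A synthetic
    phantom generator with known ground truth (Rician magnitude noise,
    controllable distortion and field perturbations) makes every analysis
    stage testable without scanner access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'constructors.R'
    'utils.R'
    'distortion.R'
    'fieldmaps.R'
    'generate-fiducial.R'
    'generate-field.R'
    'generate-piqt.R'
    'generate-qmri.R'
    'io.R'
    'mrlqa-package.R'
    'piqt-metrics.R'
    'qa-report.R'
    'qmri-fit.R'
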
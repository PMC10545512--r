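Package: cineQC
Title: Quality-Controlled Analysis of Short-Axis Cine Cardiac MR Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality-controlled quantification of biventricular
    function from short-axis (SAX) cine cardiac magnetic resonance
    segmentation stacks. Provides a canonical data model for label volumes
    (NIfTI + JSON sidecars), a rule engine for ground-truth quality
    assurance and post-analysis quality control with automatic correction of
    simple errors, ventricular volumetry (EDV, ESV, SV, EF, LV mass),
    Otsu-threshold exclusion of papillary muscles from blood pools, a
    marginalized partial-label segmentation loss for inconsistent annotation
    protocols, agreement statistics (Dice, Bland-Altman, rank tests with
    Bonferroni correction), and a synthetic cardiac phantom generator with
    analytically known biomarkers and an injector for common annotation
    defects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'biomarkers.R'
    'core_io.R'
    'defects.R'
    'evaluation.R'
    'losses.R'
    'papillary.R'
    'phantom.R'
    'pipeline.R'
    'screening.R'
    'utils.R'
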
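Package: mrfrepeat
Title: Repeatability Analysis for Simultaneous Proton MRF and Sodium Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and statistical toolkit for test-retest repeatability
    studies of quantitative brain MRI acquired with simultaneous 3D proton
    magnetic resonance fingerprinting (MRF) and sodium imaging. Provides an
    extended phase graph (EPG) simulator for gradient-spoiled variable
    flip-angle fingerprint trains, (T1, T2, B1+) dictionary construction with
    sliding-window compression and inner-product matching, digital multi-subject
    multi-scan brain phantoms with grey matter, white matter, CSF and eye
    compartments, tissue-mask binarization and the CSF / vitreous-humor
    normalizations used for proton density and sodium maps, and the
    variance-decomposition repeatability statistics (intra- and inter-subject
    variance, coefficient of variation, intraclass correlation) with
    qualitative bands and detectable-change thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
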
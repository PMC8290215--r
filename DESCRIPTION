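Package: aminopet
Title: Amino Acid PET Biological Target Volumes for Glioma Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying the added value of amino-acid-analog PET
    (e.g. 18F-FDOPA) in radiotherapy planning of high-grade glioma.
    Computes standardized uptake values by the body-weight method with
    physical decay correction, delineates biological target volumes (BTV)
    by tumor-to-normal uptake-ratio thresholds with anatomical exclusion of
    the basal ganglia, constructs clinical and planning target volumes by
    Euclidean margin expansion with anatomical barriers, and measures
    concordance between MRI-defined gross tumor volumes and PET-defined
    BTVs via the 95th-percentile Hausdorff distance, supplementary-volume
    distances, within/outside volume decomposition, isodose coverage and
    recurrence-overlap fractions.  A configurable digital brain phantom
    with closed-form ground truth supports end-to-end validation, and a
    harmonization module compares PET signal between acquisitions
    normalized to contralateral brain uptake.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
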
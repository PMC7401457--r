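Package: octaquant
Title: Quantification of OCTA Angiograms and Longitudinal Analysis of Early
    Diabetic Retinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Skeleton-based vessel-density and perfusion-density metrics on
    en face optical coherence tomography angiography (OCTA) slabs, foveal
    avascular zone (FAZ) area and circularity, classification of early
    diabetic-retinopathy disease pathways (macular edema, neurodegeneration,
    capillary dropout) against a healthy-control reference, a 10-percent
    vessel-density decrease progression rule, and the nonparametric and
    multivariate statistics used in longitudinal cohort studies of
    nonproliferative diabetic retinopathy. Includes generators for synthetic
    vascular angiograms with ground truth and synthetic longitudinal cohorts
    with a configurable correlation and decline structure, so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    tiff,
    optparse
Config/testthat/edition: 3
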
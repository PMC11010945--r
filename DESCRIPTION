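Package: fetquant
Title: Dual-Timepoint FET-PET Quantification of Glioma Infiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for semiquantitative dual-timepoint amino-acid (FET) PET
    analysis at the glioma infiltration border. Implements multi-reference
    standardized-uptake-value (SUV) and target-to-background ratio (TBR)
    scoring against contralateral brain, thalamus, choroid plexus, artery
    and venous-sinus backgrounds; published threshold and decision-tree
    classifiers separating glioma from reactive astrogliosis; a CART
    trainer with Gini split search and cross-validation cost reporting;
    ROC analysis with DeLong confidence intervals and Youden-optimal
    cutoffs; and voxelwise tumor-extent delineation on SUV volumes.
    Includes a calibrated synthetic-data module that generates biopsy
    sample tables and dual-timepoint PET phantoms emulating published
    uptake distributions, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    pROC,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    rpart,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
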
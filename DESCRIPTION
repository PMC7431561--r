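Package: crcmark
Title: Cross-Omics Biomarker Discovery and Digital IHC Prognosis for Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for taking a candidate biomarker from
    knockout-mouse multi-omics screens through to patient prognosis.
    Provides a congruence filter that intersects genotype-contrast
    microarray fold changes with proteomic fold changes to nominate
    Myc-dependent Wnt targets; digital scoring of
    hematoxylin/DAB-stained sections via colour deconvolution, a
    weighted four-zone modified H-score (0-300) and a nuclear
    positive-percentage (0-100); and cutoff-based survival analysis
    (ROC/AUC, sensitivity-specificity balanced dichotomization,
    Kaplan-Meier, log-rank, multivariate Cox). Seeded synthetic
    generators for expression tables, stained-section images with
    per-pixel ground truth, and survival cohorts make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    survival,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
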
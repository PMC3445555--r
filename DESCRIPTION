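Package: hrme
Title: Quantitative Nuclear-to-Cytoplasmic Ratio Analysis for
    Fiber-Bundle Fluorescence Microendoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the nuclear-to-cytoplasmic (N/C) area ratio
    in fluorescence microendoscopy images acquired through a coherent fiber
    bundle, and to evaluate the ratio as a diagnostic classifier. The
    pipeline covers representative-frame selection and quality control,
    region-of-interest restriction, contrast-limited adaptive histogram
    equalization, median filtering to suppress the fiber-bundle honeycomb
    pattern, threshold-based nuclear segmentation with object size
    filtering, per-site N/C computation, cohort-level group statistics, and
    ROC analysis with Q-point operating-point selection. A synthetic-frame
    generator renders fiber-bundle images of proflavine-stained epithelium
    with known ground-truth nuclear masks so that every stage can be tested
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
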
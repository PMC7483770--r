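Package: cnaprofiler
Title: Common Regions and Probability Profiles of Copy Number Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses cohorts of segmented somatic copy-number profiles
    (SEG format, e.g. Circular Binary Segmentation output) into common
    regions of alteration with a breakpoint sweep-line partition, estimates
    the per-region probability-of-alteration generator function with
    proportion confidence bands to define disease signatures, compares
    phenotypic groups by confidence-band overlap and profile distance, and
    validates the estimator with a Bernoulli cohort simulator and
    squared/percentage error convergence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
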
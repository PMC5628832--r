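Package: bfnet
Title: Boolean Function Networks for Gene Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory networks from time-course
    expression data with Boolean Function Networks (BFN). Expression profiles
    are soft-discretized by an empirical-CDF rank transform interpreted as the
    probability that a gene's hidden binary state is active. A first
    likelihood-ratio test scans ordered gene pairs for the unary Boolean
    function and time delay that best explain the target given the source; a
    second likelihood-ratio test decides, for each discovered link, whether
    the regulation is direct or mediated by an intermediate gene, comparing
    binary-function and unary-through-mediator models. The package also
    provides the complete catalogs of non-trivial unary and binary Boolean
    functions with indefinite outputs, a planted-network simulator with noisy
    Gaussian emissions for parameter-recovery studies, gold-standard
    evaluation metrics (sensitivity, specificity, precision, NPV and three
    distances from ideal performance), a Pearson-correlation ROC baseline,
    and a cell-cycle phase-succession consistency check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
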
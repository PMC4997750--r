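Package: cfScreen
Title: Shallow Whole-Genome Plasma DNA Copy-Number Screening for Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening plasma cell-free DNA for the segmental
    copy-number aberrations characteristic of high-grade serous ovarian
    carcinoma, using shallow whole-genome sequencing bin counts of the kind
    produced by clinical non-invasive prenatal testing (NIPT) platforms.
    Implements a within-sample-reference z-score copy-number caller
    (WISECONDOR-style reference bins, Stouffer-windowed scores, run-based
    segmentation), a prespecified >= 15 Mb screen-positive rule with
    annotation against a recurrent arm-level CNV catalog, a simplified
    NIPT-style whole-chromosome aneuploidy screen with no-call logic, exact
    binomial evaluation of cohort screening performance, and a seeded
    synthetic-cohort generator (GC bias, negative-binomial overdispersion,
    tumor-fraction-diluted CNV profiles) for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
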
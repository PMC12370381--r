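Package: srsdvh
Title: DVH Accuracy QA for Intracranial Stereotactic Radiosurgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the effect of CT slice thickness and dose-grid
    resolution on dose-volume-histogram (DVH) accuracy in intracranial
    stereotactic radiosurgery. Generates analytical ground-truth phantoms
    (spheres with closed-form radial dose) and clinical-like multi-lesion
    cases, computes structure and isodose volumes from planar contours by
    supersampled point-in-polygon rasterisation, derives SRS plan-quality
    indices (D95, V30Gy, Paddick conformity index, gradient index), and
    runs discretisation studies with ratio power-law fits, Spearman rank
    analysis, Wilcoxon signed-rank comparisons and paired power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
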
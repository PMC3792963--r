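Package: perivasc
Title: Quantifying Perivascular Drug Penetration from Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how far an auto-fluorescent chemotherapeutic agent
    (doxorubicin) penetrates from CD31-labelled tumor microvessels in
    multi-channel fluorescence microscopy fields. Provides calibrated raster
    types with channel binarization, exact Euclidean distance maps to the
    nearest vessel, fluorescent spot detection with per-spot nearest-vessel
    distances, Weidner hotspot microvessel-density counting, per-field and
    per-animal aggregation, treatment-arm comparison by one-way ANOVA with
    Fisher LSD post hoc tests (including summary-statistics forms that operate
    on published mean/SD tables), and a seeded forward simulator that generates
    whole synthetic studies with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
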
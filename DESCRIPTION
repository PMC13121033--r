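Package: pairtrace
Title: Isotopologue Peak-Pair Tracing for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unbiased detection of the metabolic fates of a 1:1 heavy/light
    isotope-labelled nutrient from untargeted LC-MS feature tables. Finds
    unlabelled/labelled isotopologue peak pairs separated by the tracer mass
    shift (4.0071 Da for 13C3,15N1-cysteine) after intensity, blank and
    mass-floor filtering and duplicate-feature merging; flags adduct and
    natural-isotope satellite pairs, applies stringent mass/retention-time
    filtering and cross-polarity deduplication, and names final features.
    Downstream annotation predicts elemental compositions of features and of
    their implied added masses and computes conjugate masses for candidate
    thiol reactions. Also implements supporting quantitative procedures:
    NRF2-activation scoring and classification, response-ratio calibration,
    cell-volume-hour integration, medium exchange-flux regression,
    proliferation rates, and the isotopologue detection rule for fractional
    labelling. A seeded synthetic peak-list and growth-series generator
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
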
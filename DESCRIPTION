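Package: tilscape
Title: Quantification and Prognostic Analysis of Tumour-Infiltrating
    Lymphocytes from Nuclei Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes stromal and intratumoural tumour-infiltrating
    lymphocyte (TILs) scores from per-slide nuclei centroid maps and
    region masks: tumour-associated stroma capture by morphological
    dilation and hole filling, sTILs/tTILs counts, an AI-based sTILs
    percentage, and cell-type co-occurrence features. Provides the full
    downstream cohort analysis used in digital-pathology prognostic
    studies of luminal breast cancer (rank-based association tests with
    mean ranks, intraclass correlation for visual-vs-automated
    agreement, stratified cohort splitting, outcome-based cut-point
    discovery by maximally selected log-rank statistics, Kaplan-Meier
    and Cox proportional-hazards models with per-1000-unit hazard
    ratios), plus a synthetic-data module that generates virtual slides
    and cohorts with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
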
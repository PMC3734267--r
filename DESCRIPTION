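Package: sivva
Title: Species Vulnerability Scoring, Sea-Level-Rise Exposure, and Paired
    Trait Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expert-elicited species vulnerability assessment with
    the four-module SIVVA scoring scheme (vulnerability, adaptive capacity,
    conservation value, information availability): weighted module summary
    scores, Monte-Carlo propagation of assessor uncertainty to percentile
    confidence intervals, and weight-permutation sensitivity analysis.
    Includes a bathtub sea-level-rise inundation model on gridded elevation
    with percent-of-range exposure and distance-to-coast metrics, exact
    Wilcoxon rank-sum enumeration for small paired-taxon trait comparisons,
    adjusted-logit trait normalization, Benjamini-Hochberg false-discovery
    control, likelihood-ratio tests on mixed models, and synthetic-data
    generators so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
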
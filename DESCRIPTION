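Package: cecprior
Title: Prioritizing Contaminants of Emerging Concern from Metabolite
    Profiles with Multi-Response PLS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing contaminants of emerging concern in
    multi-site biomonitoring studies of caged sentinel animals. Raw
    per-event water-contaminant panels with detection-limit censoring are
    aggregated to site maxima, metabolite abundance matrices are
    median-normalized and screened for site differences by one-way ANOVA
    with Tukey honest-significant-difference letter displays, and the two
    blocks are linked by multi-response partial least squares (NIPALS)
    regression. Contaminant responses are then selected by iterative
    backward elimination and one-by-one re-introduction under
    cross-validated CV-ANOVA significance and cumulative Q2 improvement,
    and metabolite biomarkers are ranked by variable importance in
    projection (VIP) with jackknife inference. A synthetic-study
    generator with planted low-rank exposure structure makes every stage
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
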
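Package: lipidbench
Title: Erythrocyte Membrane Fatty-Acid Lipidomic Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fatty-acid-based erythrocyte membrane lipidomics with
    gas-chromatography FAME (fatty acid methyl ester) data. Fits per-analyte
    calibration curves, back-calculates microgram-per-millilitre quantities
    from peak areas, closes a fixed 10-fatty-acid cluster to relative
    percentages, derives the standard membrane lipid indexes (family totals,
    SFA/MUFA and omega-6/omega-3 ratios, PUFA balance, unsaturation and
    peroxidation indexes), builds healthy-cohort reference intervals and
    distribution summaries, and runs normality-gated two-group comparisons and
    covariate correlations. Ships a compositional (additive-logistic-normal)
    synthetic cohort generator calibrated to published per-sex means, standard
    deviations, and covariate correlations of a healthy dog cohort, so the
    whole pipeline is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
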
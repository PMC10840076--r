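Package: bennscan
Title: Sex-Specific Height Exponents for Relative-Weight Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives sex-specific optimal height exponents for relative-weight
    indices of the Benn form weight/height^p by grid search over exponents,
    using age-adjusted partial Pearson correlations with height-independency
    and fatness-dependency criteria. Includes a seeded synthetic anthropometric
    cohort generator with a known ground-truth allometric exponent and a
    proportional-hazards mortality process, downstream evaluation of candidate
    formulas as body-fat screening tools (rank-based AUC, Youden-optimal
    cutoffs, relative-sitting-height strata, category reclassification), and a
    Cox proportional-hazards comparison of index fifths with AIC model
    comparison. The Cox partial likelihood (Efron tie correction) is fitted by
    Newton iteration within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    pROC
Config/testthat/edition: 3
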
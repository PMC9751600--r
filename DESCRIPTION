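Package: heattol
Title: Heat-Tolerance Screening of Crop Genotypes from Pollen Viability Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening heat-tolerant genotypes in multi-season field
    trials phenotyped for percent pollen viability under normal and terminal
    heat-stress conditions. Computes the pollen-viability heat susceptibility
    index (HSI) per genotype and season, classifies genotypes into tolerance
    classes and intersects tolerant sets across seasons; fits the balanced
    combined factorial analysis of variance (treatment, year, genotype,
    treatment-by-genotype); estimates variance components and the genetic
    parameters PCV, GCV, broad-sense heritability and genetic advance; and
    summarises viability distributions, HSI correlations and breeding-era
    trends. A seeded simulator generates balanced randomized-complete-block
    panels with known genetic architecture so every pipeline stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
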
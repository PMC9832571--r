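Package: matchdem
Title: Phenological Mismatch and Demography of Cavity-Nesting Bees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for nesting-flowering phenological mismatch
    in solitary, cavity-nesting bees. Estimates nesting and flowering
    phenologies as abundance-weighted mean dates, identifies each bee
    species' main floral resources from pollen loads (85 percent rule),
    scores diet generalization with Shannon diversity, imputes brood-cell
    counts from occupied cavity length, fits linear and exponential mixed
    models of recruitment against mismatch with AIC selection, and computes
    population growth rates with nest-resampling bootstrap confidence
    intervals. Includes a synthetic-data generator that emulates a
    multi-season trap-nest study so every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
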
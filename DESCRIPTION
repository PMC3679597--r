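Package: cartoaudit
Title: Auditing the Global Mapping Status of Clinically Important
    Infectious Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A quantitative framework for auditing how well the global
    geographical distributions of clinically important infectious diseases
    have been mapped. Each disease is assigned one of five recommended
    mapping options from rule-based data-availability criteria (occurrence
    literature density per endemic country, worldwide occurrence, and
    reservoir or vector range constraints). Every published map of a
    disease, vector or reservoir is scored with a three-part evidence
    quality rubric (contemporariness, diagnostic accuracy, geo-positional
    accuracy), a population-at-risk geographic scope term and a
    mapping-option ratio, combined into a 0-100 metascore with a
    satisfactory-assessment threshold. Corpus-level summaries report counts
    by option, transmission route and aetiological agent, best-map radial
    series and binary country-level endemicity exports. A seeded synthetic
    corpus generator, including exact constructive matching of requested
    marginal counts, stands in for proprietary clinical disease databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
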
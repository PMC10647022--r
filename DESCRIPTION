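Package: rxnroles
Title: Argument-Role Annotation and Extraction for Organic Synthesis Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for representing organic-synthesis procedure text as
    actions with PropBank-style argument roles. Provides domain types and
    validation for a six-label entity / four-label relation annotation schema,
    a chemistry roleset registry with verb lemmatization, brat standoff
    reading and writing with procedure-text preprocessing, IOB2 and
    entity-marker training-view exports, a deterministic rule-based
    extraction pipeline, exact and relaxed span-matching evaluation,
    conversion of annotated procedures into ordered action sequences, and a
    seeded generator of schema-conformant synthetic corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    jsonlite,
    yaml,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
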
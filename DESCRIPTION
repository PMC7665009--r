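Package: ontochron
Title: Hierarchical Analysis of Ontogenetic Time and Detection of
    Developmental Heterochronies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Treats developmental time as a hierarchy: rows of a binary
    presence/absence matrix are species-by-time-landmark operational
    taxonomic units built from staging schedules normalized to
    percent-of-development in degree-Celsius-days.  Provides exact
    (branch-and-bound) and heuristic maximum-parsimony searches rooted at
    an all-absent ancestor, Fitch/Sankoff scoring with missing data,
    zero-length-branch condensation of equally parsimonious trees,
    ensemble consistency and retention indices, strict consensus, ACCTRAN
    character-change mapping, and set-based and tree-based detection of
    heterochronies (a species 'late' or 'advanced' at a time landmark)
    with their diagnostic characters.  Includes a synthetic-schedule
    generator with injectable heterochronic shifts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
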
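Package: rtsites
Title: Normalization of Free-Text Radiation Treatment Site Names to Coded Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps the free-text treatment-site labels that radiation oncology
    record-and-verify systems accept into coded concepts (UMLS-style concept
    identifiers plus semantic types). Builds a task-specific lexicon from a
    semantic-type-filtered concept source merged with a curated supplement of
    radiotherapy abbreviations, tokenizes site names, resolves unknown tokens
    with bigram-context candidate generation ranked by Levenshtein distance,
    assembles maximal dictionary terms, and scores the output against
    gold-standard annotations with entity-level recall and precision. Includes
    descriptive corpus statistics, a seeded synthetic-corruption generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
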
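Package: ternr
Title: Temporal Expression Recognition and Normalization for Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for temporal expression recognition and normalization
    (TERN) in clinical narrative text. Recognizes temporal phrases with a
    rule/dictionary front end producing fine-grained SCATE-style entities,
    converts them to TimeML TIMEX3 annotations with ISO-8601 normalized
    values, and disambiguates relative expressions as DATE versus DURATION
    with a linear support vector machine over phrase features built from
    contextual (sub)word embeddings. Includes corpus filters for the
    DATE/DURATION and relative/implicit/vague annotation subsets, span- and
    class-based evaluation with gold-support weighted averages and bootstrap
    confidence intervals, error-category analysis, dataset builders for
    binary and BIO/Ttype token-classification fine-tuning tasks, and a
    deterministic synthetic discharge-summary generator with gold standoff
    annotations so the full pipeline can be exercised without access to
    restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
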
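Package: sbmlannot
Title: Annotation Recommendation for SBML Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recommends ontology annotations for elements of SBML models.
    Species are matched against a reference dictionary of ChEBI-style terms by
    cosine similarity of 36-dimensional character-count vectors of names and
    synonyms; reactions are matched against Rhea-style reference reactions by
    the overlap of their participants' hydrogen-simplified chemical formulas,
    normalized by the smallest best-matching reference reaction. Includes
    match-score selection criteria (top / above a cutoff), iterative
    cross-refinement of species and reaction predictions via participant
    pairing, prediction-quality metrics (nonempty, accuracy, exactness),
    SBML read/write of controlled-vocabulary annotations, a deterministic
    synthetic-data generator for end-to-end testing, and command-line scripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
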
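Package: ontoqc
Title: Semiotic Quality Scoring for OWL Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores OWL 2 ontologies on the semiotic quality framework:
    syntactic (lawfulness, richness), semantic (interpretability, clarity,
    consistency), pragmatic (comprehensiveness, accuracy, relevancy) and
    social (authority, history) sub-scores combined into a weighted overall
    quality score. Includes a label normalization pipeline, pluggable
    word-sense lexicon lookup, template-based verbalization of logical
    axioms into English for domain-expert review, a CSV review round-trip,
    session snapshots, and a deterministic synthetic-ontology generator for
    testing. Reads RDF/XML and Turtle serializations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
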
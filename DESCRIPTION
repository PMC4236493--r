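Package: ontomatch
Title: Large-Scale Ontology Matching with Lexical Indexing and Contextual Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes scored equivalence mappings between the concepts and
    properties of two ontologies (OWL RDF/XML, Turtle, RDFS, SKOS, or OBO).
    Entities are rendered as fielded virtual documents, normalized through a
    stopword/stemming/permutation filter chain, and indexed in a tf-idf
    vector-space inverted index; candidate mappings are retrieved by two-way
    search, scored with a weighted string-similarity ensemble (ISub, q-gram,
    Levenshtein), extended via synonym-lexicon bridging, and complemented by a
    decision-tree contextual stage that classifies pairs drawn from the
    neighbourhood of high-precision anchor mappings. Candidates are repaired by
    disjointness and criss-cross consistency filters, selected greedily, and
    evaluated against reference alignments with precision, recall and
    F-measure. Includes a synthetic biomedical-style ontology-pair generator
    for benchmarking, and readers/writers for the OAEI Alignment RDF format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    stats,
    tools,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
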
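Package: ontoquery
Title: Ontology-Based Query Reformulation over Annotated Information Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reformulates concept-based (description-logic style) queries over
    semantically annotated UML-style information models into executable
    object-oriented queries (CQL and its distributed extension DCQL).
    Provides a customised UML-to-OWL transformation with explicit inherited
    associations and an OWL list pattern for annotation qualifier sequences,
    lightweight EL-style reasoning services (classification, satisfiability,
    association-path finding), semantic discovery of federated join
    conditions from shared concept annotations, and a monoid-comprehension
    intermediate representation with a reference evaluator. Ships toy
    fixtures of two biomedical data-service models (a caBIO-like and a
    PIR-like fragment), a synthetic model generator, and command-style
    entry points for ontology generation, query reformulation and path
    metrics.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
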
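Package: tmaowl
Title: Tissue Microarray Provenance as OWL/RDF Linked Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represent tissue-microarray (TMA) provenance -- array, block,
    slide, core-in-block and core-on-slide -- as Linked Data. Provides the
    minimal TMA OWL vocabulary as a typed object model, stable HTTP URI
    minting with CURIE/fragment expansion and compaction, RDF/XML, Turtle
    and N-Triples read/write with deterministic canonicalization and
    blank-node-aware graph isomorphism, schema validation with inverse
    object-property materialization, conversion of well-defined TMA XML
    into OWL instance documents, linkage of cores to external-ontology
    terms (diagnoses, microarray experiments), a seeded synthetic-fixture
    generator with rule-targeted mutations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
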
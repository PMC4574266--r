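Package: owlstore
Title: In-Memory RDF Triple Store with Strict RDF/XML Loading and OWL 2
    Axiom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A compact, index-backed in-memory RDF triple store for working
    with OWL ontologies. Terms (IRIs, literals, blank nodes), namespace
    prefixes and document descriptors are interned to light-weight integer
    identifiers; triples are held in configurable bin-and-sort indices and
    searched with an automatic query planner. Ontology documents in RDF/XML
    syntax are loaded transactionally (a failed load leaves the store
    untouched), with owl:imports resolved against a filesystem catalog.
    Stored triples are translated into OWL 2 axioms following the W3C
    RDF-graph mapping with strict validation (undeclared predicates and
    misspelled standard vocabulary terms abort the translation), and axioms
    are serialized to functional-style syntax. Includes a synthetic ontology
    generator for testing and an index-configuration benchmark, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'errors.R'
    'vocab.R'
    'AllClasses.R'
    'store.R'
    'find.R'
    'rdfxml.R'
    'load.R'
    'catalog.R'
    'axioms.R'
    'serialize.R'
    'fixtures.R'
    'cli.R'
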
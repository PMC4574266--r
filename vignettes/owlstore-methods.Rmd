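---
title: "owlstore: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{owlstore: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlstore)
```

This vignette explains what `owlstore` computes and why it is built the
way it is: the data model, the index and planner design, the strictness
rules of the loader and the axiom translator, what the synthetic-ontology
generator does and does not emulate, and the numerical and design choices
a maintainer would want spelled out.

## The data model

An RDF term is one of three things. An **IRI node** is stored as a
namespace prefix (everything up to and including the last `#`, else the
last `/`) plus a fragment; concatenating the two reconstructs the input
byte-for-byte, which is why this split was chosen — it also matches how
ontology IRIs are structured in practice (`...obo/OBI_0000070`,
`...owl#Class`). A **literal** carries a datatype IRI, a typed payload and
an optional language tag. A **blank node** carries the document it came
from and an ordinal within that document.

Every term, namespace and document descriptor is interned: stored once and
referred to by an integer ID. Interning gives three things at once — a
compact store (a triple is four integers), O(1) equality tests during
search, and well-defined identity semantics:

* IRI identity is string identity.
* Literal identity is *(datatype, canonical payload, language)*, not
  lexical identity: `"1"^^xsd:boolean` and `"true"^^xsd:boolean` intern to
  the same node, as do `"007"^^xsd:int` and `"7"^^xsd:int`. Canonical
  forms: `true`/`false` for booleans, sign-plus-digits with leading zeros
  stripped for the integer family, C `%.17g` rendering of the parsed
  double for `decimal`/`float`/`double`, and the raw lexical form for
  strings and all other datatypes. Language tags are only legal on
  plain/string-typed literals.
* Blank-node identity is *(document, source label)*. Two documents using
  the same label `_:b1` always get distinct nodes; this is what makes
  loading many documents into one store safe.

The standard RDF, RDFS, OWL 2 and XSD vocabularies are interned into every
fresh store first, in a fixed table order, so their IDs are constants
(`vocabId("owl:Class")`) identical across stores and runs. This mirrors
compile-time vocabulary constants in systems languages; any fixed
deterministic order suffices, and ours is the order of the vocabulary
table in `R/vocab.R`.

Triples are **generalized**: the store enforces no positional typing, so a
literal subject is representable. Normal parsing never produces one, but
the container does not forbid it — type discipline belongs to the OWL
layer, not the triple layer. A triple also carries its source document,
and the document participates in triple identity: the same *(s, p, o)*
asserted by two documents is two triples, while re-asserting a triple
within one document is collapsed to one. The duplicate-within-a-document
case is genuinely underdetermined in RDF practice; we collapse because the
statement multiset of a single document has set semantics in RDF.

## Indices and the query planner

An index layout `"s:pod"` bins triples by subject and sorts each bin by
predicate, then object, then document. The store holds any non-empty set
of layouts, fixed at construction; the default pair `s:pod, o:psd`
serves the two access paths that dominate axiom generation — *subject(+
predicate)* and *object(+predicate)* lookups.

Indices are maintained **lazily**: insertion only records the triple, and
the first query after a batch of insertions re-sorts the permutation
(O(n log n), radix order). For the load-then-query workflow this is
strictly cheaper than incremental sorted insertion; interleaved
insert/query workloads pay one rebuild per batch boundary.

The planner: among indices whose bin key the pattern constrains, pick the
one whose sort order covers the most *additionally* constrained keys as a
prefix; ties break by index declaration order (reproducibility); no
usable index means a linear scan. Matching within an index is binary
search on the bin, then on each covered prefix key; remaining constraints
are filtered linearly, short-circuit, in the fixed order s, p, o, d.

For the index-configuration study (`indexStudy()`), work is measured in
**element comparisons** rather than wall-clock time: one comparison per
binary-search probe, one per candidate row per constrained key actually
tested. This makes the benchmark exact, deterministic and
hardware-independent, and it reproduces the *direction* of the effect —
on a random-subject + `rdfs:subClassOf` workload over 10,000 triples the
default two-index configuration does roughly two orders of magnitude less
comparison work than a scan — without asserting anything about seconds.

## Loading: strictness and transactions

Loading has four stages, and every failure is tagged with one: `file`
(unreadable path), `xml` (not well-formed; delegated to libxml2 via
`xml2`), `rdf` (an RDF/XML violation: duplicate `rdf:ID`, a relative IRI
with no base, an unknown `rdf:parseType`, a non-namespaced attribute, a
literal that cannot be parsed under its declared datatype, ...), and `owl`
(a broken ontology header — e.g. two `owl:Ontology` headers — or an
unresolvable import).

The transactional guarantee — after a failed load the store is exactly as
before — is implemented by journaling. Every store mutation is an append
(tables grow; hash-map keys are added; nothing is ever deleted or
overwritten), so a transaction records the table sizes at entry plus every
key added while active, and rollback truncates and removes. An imports
closure runs inside a single transaction: if any document of the closure
fails, none of them is kept.

The RDF/XML interpretation itself (the striping of node elements and
property elements, subject forms, property attributes,
`parseType="Resource"/"Collection"/"Literal"`, `rdf:li`, reification via
`rdf:ID` on property elements, `xml:base`/`xml:lang` scoping) is
implemented here on top of the XML DOM; only XML well-formedness,
encodings and namespace resolution are delegated to `xml2`.
`parseType="Literal"` content is kept as a string literal of type
`rdf:XMLLiteral` preserving the raw serialization; full XML
canonicalization is out of scope. Documents lacking an `owl:Ontology`
header are legal at the RDF level and are registered with an absent
ontology IRI.

Imports are resolved against an `OntologyCatalog` built by scanning a
directory: every file whose content yields an ontology header is entered
with its ontology IRI and version IRI. Resolution prefers an exact
version-IRI match, then an ontology-IRI match; among several versions of
one ontology the lexicographically greatest version IRI wins — a
deterministic stand-in for "latest version". Import IRIs are never
fetched from the network; without a catalog, imports are ignored (logged
at `options(owlstore.verbose = TRUE)`), and with a catalog an
unresolvable import is an `owl`-stage error. Documents are de-duplicated
by ontology/version IRI and by path, which also terminates import cycles.

## Triple → axiom translation

`mapAxioms()` follows the W3C RDF-graph mapping in two passes over its
scope (the whole store or one document): declarations first, then axiom
triples. The supported surface is: declarations of the six entity kinds;
`SubClassOf`, `EquivalentClasses`, `DisjointClasses` with full class
expressions (intersections, unions, complements, enumerations, and
existential / universal / value / cardinality restrictions, qualified
included); sub-property, domain and range axioms for object, data and
annotation properties; the functional, inverse-functional, transitive and
symmetric characteristics; class, object-property, data-property and
annotation assertions (with reified `owl:Axiom` annotation blocks
attached to their axioms); and the ontology header with its imports,
header annotations becoming ontology annotations.

Strictness rules, each with its own error class:

* **Misspelled standard terms.** Any IRI whose namespace is rdf/rdfs/owl/
  xsd but which is not in the standard vocabulary (`owl:Classs`) aborts
  before anything else is interpreted. The check is cheap because
  vocabulary nodes are exactly the constant IDs.
* **Undeclared predicates.** A predicate that is neither built-in
  vocabulary nor a declared object/data/annotation property aborts.
  Built-in annotation properties (`rdfs:label`, `rdfs:comment`,
  `owl:versionInfo`, ...) need no declaration — requiring one would
  reject essentially every real ontology.
* **Declaration conflicts.** An entity declared both object and data
  property is an error; punning (class + individual) is allowed, per
  OWL 2.
* **Structural violations.** Malformed RDF lists (missing/duplicated
  links, branches, shared tails, cycles), restrictions without
  `owl:onProperty` or with other than exactly one filler key, non-integer
  or negative cardinality literals, cyclic expressions, and any extra
  triple hanging off a blank expression node.
* **Completeness.** Every triple in scope must be consumed exactly once
  — as a declaration, an axiom trigger, part of an expression or list, or
  an annotation. Leftovers abort. Constructs we recognize but do not map
  (property chains, `owl:hasKey`, negative assertions, `owl:inverseOf`,
  `owl:sameAs`, `AllDifferent`/`AllDisjoint*` lists, datatype facets, ...)
  are reported as "unsupported construct" errors rather than dropped:
  failing loudly is the point.

Translation is atomic by construction: errors are R conditions raised
before the function returns, so no partial axiom list is observable.

One ordering subtlety is worth recording. An assertion triple whose
subject is a blank node is deferred until all other axioms have been
mapped: if that blank node meanwhile turned out to anchor a class
expression, the assertion is an illegal extra triple on the expression
node, and deferral is what makes the check independent of triple order in
the document.

Serialization (`serializeFunctional()`) is deterministic: declarations
first, then axioms sorted by kind and rendered text; unordered operand
sets (equivalence/disjointness pairs, annotation lists) sort by rendered
string, while RDF-list-backed operands keep source order because RDF
collections are ordered. Prefixes are assigned deterministically (the
standard four by name, others from the last path segment of the namespace
IRI, de-duplicated with numeric suffixes). `axiomStrings()` renders the
same axioms with full IRIs — the canonical, prefix-independent form used
in all comparisons and tests.

## The synthetic-ontology generator

`generateOntologyDocument()` produces RDF/XML documents whose expected
statement multiset, axiom multiset and blank-node count are known in
closed form: a header with optional imports, class and object-property
declarations, named subclass links (distinct ordered pairs), existential
restrictions as anonymous superclasses (`someValuesFrom`; one blank node
and four statements each), and distinct `rdfs:label` annotations. One
statement per fact and unique annotation texts keep the closed-form count
exact under store de-duplication. Generation is deterministic under the
spec seed, and the generator predicts even the labels the parser assigns
to anonymous blanks, so round-trip comparisons can be exact.

Error injection produces documents that fail at a named stage: truncated
bytes (`xml`), a duplicated `rdf:ID` (`rdf`), a second ontology header
(`owl` at load time), an undeclared predicate or a misspelled OWL term
(`owl` at translation time). The latter two load cleanly as RDF —
deliberately, since that is precisely the class of error strict
translation exists to catch.

What the generator does **not** emulate: the scale (hundreds of MB), term
frequency distributions, annotation richness, container/collection usage
and cross-ontology reuse patterns of real ontologies, nor anonymous
individuals or data-property assertions. Passing tests therefore
demonstrate correctness of the machinery on the constructs it claims to
support, not performance or coverage on any specific real-world ontology.

Workloads (`generateWorkload()`) mirror the classic triple-search
benchmark: subjects drawn uniformly from the store's subject pool with
the fixed predicate `rdfs:subClassOf`, plus an `all16` mode that drifts
uniformly over the 16 constrained/wildcard pattern combinations for
oracle testing.

## Problem sizes and verification

The test suite verifies search against a brute-force linear-scan filter
on 20 randomized stores of 10,000 triples across all 16 pattern
combinations, and the same patterns under one-, two- and four-index
configurations; transactional rollback on 36 error-injected documents via
deep store snapshots; blank scoping across six documents sharing labels;
generator closure on 100 seeded specs; and the index study on a
200-query workload. These sizes exercise every code path (multi-bin
binary search, residual filtering, scan fallback, rebuilds after batched
insertion) while keeping the full suite under a minute; the properties
checked are size-invariant.

Two independent cross-checks run in the suite: Python `rdflib` parses the
same bytes and the statement multisets are compared up to blank renaming
(graph isomorphism), and a separately written rdflib-based translator
(`inst/oracle/axioms_oracle.py`, which navigates the triple graph with a
different API in a different language) derives the axiom strings for the
same documents. The R implementation and the Python oracle share only the
canonical string format, not code.

## Known limitations

* RDF/XML is the only input syntax; there is no serialization back to
  RDF/XML and no Turtle/Manchester/OWL-XML support.
* No reasoning: axioms are produced for inspection and export, not
  classified; no consistency checking.
* The OWL 2 surface excludes property chains, keys, negative assertions,
  inverse properties, datatype restrictions and the `All*` list axioms —
  all detected and reported, never mis-mapped.
* No persistence, no SPARQL, no triple deletion; the store is append-only
  by design (that is also what makes transactions cheap).
* No concurrency primitives: read-only operations may be interleaved, but
  a mutating operation requires exclusive access, as with base R
  environments generally.
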
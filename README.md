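# owlstore

An in-memory RDF triple store for working with OWL 2 ontologies, with a
strict RDF/XML loader and a strict RDF-graph → OWL-axiom translator.

Biomedical ontologies (the OBO family, OBI, Uberon, ...) are distributed as
RDF/XML documents. Working with them programmatically means parsing those
documents into RDF triples *(subject, predicate, object)*, storing and
searching the triples efficiently, and translating the triple graph into
OWL 2 axioms — `SubClassOf(A B)`, `Declaration(Class(A))`,
`ObjectSomeValuesFrom(p C)` and so on — that a reasoner or a curator can
consume. `owlstore` implements that pipeline for R users who need to load,
inspect, query and validate ontologies, with an emphasis on two properties
that matter in practice:

* **Compact, fast search.** Every namespace prefix IRI, RDF term and
  document descriptor is interned once and referred to by a light-weight
  integer ID; the standard RDF/RDFS/OWL/XSD vocabulary has fixed constant
  IDs. Triples are quadruples of IDs *(s, p, o, document)* held in a
  configurable set of **bin-and-sort indices**: an index bins triples by
  one term and sorts each bin by the other three, so a pattern such as
  *subject + predicate* is answered by two binary searches instead of a
  scan. `findTriple()` picks the best index for each pattern
  automatically; with no usable index it falls back to a linear scan, so
  results never depend on the configuration.

* **Strict, transactional interpretation.** A document either loads
  completely or not at all: any failure — unreadable file, malformed XML,
  an RDF/XML violation, a broken OWL header — rolls the store back to its
  exact prior state. Axiom translation follows the W3C RDF-graph mapping
  and is equally strict: every triple must be consumed exactly once, an
  undeclared predicate or a misspelled standard term (e.g. `owl:Classs`)
  aborts the whole translation with a specific error, and recognized but
  unsupported constructs are reported rather than silently mis-mapped.

`owl:imports` are resolved offline against a catalog built by scanning a
directory (`scanOntologyDir()`); the imports closure is loaded recursively,
cycle-safely, inside one transaction. Nothing is ever fetched from the
network.

## A worked example

```r
library(owlstore)

st <- TripleStore()                      # default indices: s:pod + o:psd

# a small synthetic ontology with known expectations
spec <- ontologySpec(nClasses = 4, nObjectProperties = 1,
                     nSubclassLinks = 2, nRestrictions = 1,
                     nAnnotations = 1, seed = 8)
g <- generateOntologyDocument(spec)
writeLines(g$xml, "demo.owl")

doc <- loadOntologyFile(st, "demo.owl")
st
#> TripleStore: 13 triples, 164 nodes, 6 namespaces, 1 documents
#>   indices: s:pod, o:psd
```

13 triples: one `owl:Ontology` header, five entity declarations, two named
subclass links, four triples for the anonymous existential restriction,
and one label. Pattern search works on interned IDs:

```r
findTriple(st, subj = lookupIri(st, "http://example.org/onto0008#C1"))
#>   subj pred obj doc
#> 1  158    1  38   1          # (C1, rdf:type, owl:Class) — 38 is the owl:Class constant
```

Translating the store to OWL 2 functional-style syntax:

```r
ax <- mapAxioms(st)
cat(serializeFunctional(ax, st))
#> Prefix(onto0008:=<http://example.org/onto0008#>)
#> ...
#> Ontology(exampleorg:onto0008
#> Declaration(Class(onto0008:C1))
#> ...
#> SubClassOf(onto0008:C2 ObjectSomeValuesFrom(onto0008:p1 onto0008:C4))
#> SubClassOf(onto0008:C2 onto0008:C1)
#> AnnotationAssertion(rdfs:label onto0008:C3 "label 1"@en)
#> )
```

The same workflow is available from the shell via the installed script
(`system.file("scripts", "owlstore", package = "owlstore")`):

```text
$ owlstore load demo.owl        # per-document term/triple statistics
document        IRI  Literal  Blank  Triples
/tmp/demo.owl   15   1        1      13
TOTAL           15   1        1      13

$ owlstore bench demo.owl --queries 50
config       comparisons  results
scan         736          54
s:pod,o:psd  527          54
```

`bench` reruns the store's query planner under different index layouts on
a *random subject + rdfs:subClassOf* workload and counts element
comparisons — identical answers, less work with the right index. Other
subcommands: `query`, `axioms` (writes an `.ofn` file), `validate`
(PASS/FAIL with the strict checks), `catalog`.

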
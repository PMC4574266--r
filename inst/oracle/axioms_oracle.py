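#!/usr/bin/env python
"""Independent RDF-graph -> OWL 2 axiom derivation used as a test oracle.

Reads RDF/XML ontology documents with rdflib and derives the OWL 2 axioms
of the supported subset directly from the triples, following the W3C
RDF-graph mapping. Axioms are printed as canonical functional-style-syntax
strings with full IRIs, one per line, sorted, between "## FILE <path>" and
"## END" markers. Anything outside the supported subset raises, so a
mismatch in scope fails loudly instead of silently passing.

This implementation is deliberately independent of any non-rdflib OWL
library: it navigates the rdflib Graph API only.
"""
import sys

from rdflib import Graph, RDF, RDFS, OWL, XSD, URIRef, BNode, Literal

RDFNS = str(RDF)
PLAIN_TYPES = {str(RDF) + "PlainLiteral", str(RDF) + "langString",
               str(XSD) + "string"}
INTEGER_TYPES = {str(XSD) + t for t in (
    "integer", "int", "long", "short", "byte", "nonNegativeInteger",
    "positiveInteger", "nonPositiveInteger", "negativeInteger",
    "unsignedLong", "unsignedInt", "unsignedShort", "unsignedByte")}
REAL_TYPES = {str(XSD) + t for t in ("decimal", "float", "double")}

DECL_KINDS = {
    OWL.Class: "Class",
    OWL.ObjectProperty: "ObjectProperty",
    OWL.DatatypeProperty: "DataProperty",
    OWL.AnnotationProperty: "AnnotationProperty",
    OWL.NamedIndividual: "NamedIndividual",
    RDFS.Datatype: "Datatype",
}

BUILTIN_ANN = {RDFS.label, RDFS.comment, RDFS.seeAlso, RDFS.isDefinedBy,
               OWL.deprecated, OWL.versionInfo, OWL.backwardCompatibleWith,
               OWL.incompatibleWith, OWL.priorVersion}

CHARACTERISTICS = {
    OWL.FunctionalProperty: "Functional",
    OWL.InverseFunctionalProperty: "InverseFunctional",
    OWL.TransitiveProperty: "Transitive",
    OWL.SymmetricProperty: "Symmetric",
}


def esc(s):
    return s.replace("\\", "\\\\").replace('"', '\\"')


def render_literal(lit):
    dt = str(lit.datatype) if lit.datatype else str(RDF) + "PlainLiteral"
    lex = str(lit)
    if dt in PLAIN_TYPES:
        out = '"%s"' % esc(lex)
        if lit.language:
            out += "@%s" % lit.language
        return out
    if dt == str(XSD) + "boolean":
        lex = "true" if lex.strip() in ("true", "1") else "false"
    elif dt in INTEGER_TYPES:
        v = lex.strip().lstrip("+")
        neg = v.startswith("-")
        v = v.lstrip("-").lstrip("0") or "0"
        lex = ("-" + v) if neg and v != "0" else v
    elif dt in REAL_TYPES:
        lex = "%.17g" % float(lex)
    return '"%s"^^<%s>' % (esc(lex), dt)


class Oracle:
    def __init__(self, graph):
        self.g = graph
        self.decl = {}
        for node, kind in DECL_KINDS.items():
            pass
        for s, _, o in graph.triples((None, RDF.type, None)):
            if o in DECL_KINDS and isinstance(s, URIRef):
                self.decl.setdefault(str(s), set()).add(DECL_KINDS[o])
        for p in BUILTIN_ANN:
            self.decl.setdefault(str(p), set()).add("AnnotationProperty")
        for t in ("Thing", "Nothing"):
            self.decl.setdefault(str(OWL) + t, set()).add("Class")

    def has_kind(self, node, kind):
        return kind in self.decl.get(str(node), set())

    def iri(self, node):
        assert isinstance(node, URIRef), "expected IRI, got %r" % node
        return "<%s>" % node

    def ind(self, node):
        return self.iri(node)

    def rdf_list(self, head):
        out = []
        while head != RDF.nil:
            out.append(next(self.g.objects(head, RDF.first)))
            head = next(self.g.objects(head, RDF.rest))
        return out

    def ce(self, node):
        g = self.g
        if isinstance(node, URIRef):
            assert self.has_kind(node, "Class"), "undeclared class %s" % node
            return self.iri(node)
        assert isinstance(node, BNode)
        if (node, RDF.type, OWL.Restriction) in g:
            prop = next(g.objects(node, OWL.onProperty))
            obj = self.has_kind(prop, "ObjectProperty")
            pre = "Object" if obj else "Data"
            p = self.iri(prop)

            def filler(x):
                return self.ce(x) if obj else self.iri(x)

            for pred, word in ((OWL.someValuesFrom, "SomeValuesFrom"),
                               (OWL.allValuesFrom, "AllValuesFrom")):
                vals = list(g.objects(node, pred))
                if vals:
                    return "%s%s(%s %s)" % (pre, word, p, filler(vals[0]))
            vals = list(g.objects(node, OWL.hasValue))
            if vals:
                v = vals[0]
                vs = render_literal(v) if isinstance(v, Literal) else self.ind(v)
                return "%sHasValue(%s %s)" % (pre, p, vs)
            for pred, word, qual in (
                    (OWL.minCardinality, "Min", False),
                    (OWL.maxCardinality, "Max", False),
                    (OWL.cardinality, "Exact", False),
                    (OWL.minQualifiedCardinality, "Min", True),
                    (OWL.maxQualifiedCardinality, "Max", True),
                    (OWL.qualifiedCardinality, "Exact", True)):
                vals = list(g.objects(node, pred))
                if vals:
                    n = int(vals[0])
                    if qual:
                        qpred = OWL.onClass if obj else OWL.onDataRange
                        f = filler(next(g.objects(node, qpred)))
                        return "%s%sCardinality(%d %s %s)" % (pre, word, n, p, f)
                    return "%s%sCardinality(%d %s)" % (pre, word, n, p)
            raise AssertionError("restriction without filler: %s" % node)
        for pred, word in ((OWL.intersectionOf, "ObjectIntersectionOf"),
                           (OWL.unionOf, "ObjectUnionOf")):
            vals = list(g.objects(node, pred))
            if vals:
                ops = [self.ce(m) for m in self.rdf_list(vals[0])]
                return "%s(%s)" % (word, " ".join(ops))
        vals = list(g.objects(node, OWL.complementOf))
        if vals:
            return "ObjectComplementOf(%s)" % self.ce(vals[0])
        vals = list(g.objects(node, OWL.oneOf))
        if vals:
            ops = [self.ind(m) for m in self.rdf_list(vals[0])]
            return "ObjectOneOf(%s)" % " ".join(ops)
        raise AssertionError("not a class expression: %s" % node)

    def axioms(self):
        g = self.g
        out = []

        ontos = list(g.subjects(RDF.type, OWL.Ontology))
        assert len(ontos) <= 1, "oracle supports at most one header"
        for onto in ontos:
            vers = list(g.objects(onto, OWL.versionIRI))
            if vers:
                out.append("Ontology(%s %s)" % (self.iri(onto),
                                                self.iri(vers[0])))
            else:
                out.append("Ontology(%s)" % self.iri(onto))
            for imp in g.objects(onto, OWL.imports):
                out.append("Import(%s)" % self.iri(imp))

        for s, _, o in g.triples((None, RDF.type, None)):
            if o in DECL_KINDS and isinstance(s, URIRef):
                out.append("Declaration(%s(%s))" % (DECL_KINDS[o],
                                                    self.iri(s)))

        for s, o in g.subject_objects(RDFS.subClassOf):
            out.append("SubClassOf(%s %s)" % (self.ce(s), self.ce(o)))
        for s, o in g.subject_objects(OWL.equivalentClass):
            ops = sorted([self.ce(s), self.ce(o)])
            out.append("EquivalentClasses(%s)" % " ".join(ops))
        for s, o in g.subject_objects(OWL.disjointWith):
            ops = sorted([self.ce(s), self.ce(o)])
            out.append("DisjointClasses(%s)" % " ".join(ops))

        for s, o in g.subject_objects(RDFS.subPropertyOf):
            for kind, word in (("ObjectProperty", "SubObjectPropertyOf"),
                               ("DataProperty", "SubDataPropertyOf"),
                               ("AnnotationProperty", "SubAnnotationPropertyOf")):
                if self.has_kind(s, kind):
                    out.append("%s(%s %s)" % (word, self.iri(s), self.iri(o)))
                    break
            else:
                raise AssertionError("subPropertyOf on undeclared %s" % s)
        for s, o in g.subject_objects(RDFS.domain):
            if self.has_kind(s, "ObjectProperty"):
                out.append("ObjectPropertyDomain(%s %s)" % (self.iri(s),
                                                            self.ce(o)))
            elif self.has_kind(s, "DataProperty"):
                out.append("DataPropertyDomain(%s %s)" % (self.iri(s),
                                                          self.ce(o)))
            else:
                out.append("AnnotationPropertyDomain(%s %s)" % (self.iri(s),
                                                                self.iri(o)))
        for s, o in g.subject_objects(RDFS.range):
            if self.has_kind(s, "ObjectProperty"):
                out.append("ObjectPropertyRange(%s %s)" % (self.iri(s),
                                                           self.ce(o)))
            elif self.has_kind(s, "DataProperty"):
                out.append("DataPropertyRange(%s %s)" % (self.iri(s),
                                                         self.iri(o)))
            else:
                out.append("AnnotationPropertyRange(%s %s)" % (self.iri(s),
                                                               self.iri(o)))

        for s, _, o in g.triples((None, RDF.type, None)):
            if o in CHARACTERISTICS:
                word = CHARACTERISTICS[o]
                if word == "Functional" and self.has_kind(s, "DataProperty"):
                    out.append("FunctionalDataProperty(%s)" % self.iri(s))
                else:
                    out.append("%sObjectProperty(%s)" % (word, self.iri(s)))

        handled_types = set(DECL_KINDS) | set(CHARACTERISTICS) | {
            OWL.Ontology, OWL.Restriction, OWL.Class}
        for s, _, o in g.triples((None, RDF.type, None)):
            if o in handled_types:
                continue
            out.append("ClassAssertion(%s %s)" % (self.ce(o), self.ind(s)))

        skip_preds = {RDF.type, RDFS.subClassOf, RDFS.subPropertyOf,
                      RDFS.domain, RDFS.range, OWL.equivalentClass,
                      OWL.disjointWith, OWL.versionIRI, OWL.imports,
                      OWL.onProperty, OWL.someValuesFrom, OWL.allValuesFrom,
                      OWL.hasValue, OWL.minCardinality, OWL.maxCardinality,
                      OWL.cardinality, OWL.minQualifiedCardinality,
                      OWL.maxQualifiedCardinality, OWL.qualifiedCardinality,
                      OWL.onClass, OWL.onDataRange, OWL.intersectionOf,
                      OWL.unionOf, OWL.complementOf, OWL.oneOf, RDF.first,
                      RDF.rest}
        for s, p, o in g:
            if p in skip_preds:
                continue
            if self.has_kind(p, "ObjectProperty"):
                out.append("ObjectPropertyAssertion(%s %s %s)" %
                           (self.iri(p), self.ind(s), self.ind(o)))
            elif self.has_kind(p, "DataProperty"):
                out.append("DataPropertyAssertion(%s %s %s)" %
                           (self.iri(p), self.ind(s), render_literal(o)))
            elif self.has_kind(p, "AnnotationProperty"):
                if ontos and s == ontos[0]:
                    continue  # ontology annotations: out of oracle scope
                val = (render_literal(o) if isinstance(o, Literal)
                       else self.iri(o))
                out.append("AnnotationAssertion(%s %s %s)" %
                           (self.iri(p), self.ind(s), val))
            else:
                raise AssertionError("unhandled predicate %s" % p)
        return sorted(out)


def main(paths):
    for path in paths:
        g = Graph()
        g.parse(path, format="xml")
        print("## FILE %s" % path)
        for line in Oracle(g).axioms():
            print(line)
        print("## END")
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
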
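#!/usr/bin/env python
"""Cross-check RDF/XML parses against rdflib.

Usage: triples_oracle.py a.rdf a.nt [b.rdf b.nt ...]

Each pair is (RDF/XML document, N-Triples rendering of the statements some
other parser produced for it). The two graphs are compared for isomorphism
(blank-node renaming allowed) with rdflib.compare. Prints one line per
pair: "OK <file>" or "FAIL <file>" plus diff details; exits non-zero on
any failure.
"""
import sys

import rdflib
from rdflib import Graph
from rdflib.compare import to_isomorphic, graph_diff


def main(argv):
    if len(argv) < 2 or len(argv) % 2 != 0:
        print("usage: triples_oracle.py <rdfxml> <ntriples> [...]",
              file=sys.stderr)
        return 2
    failures = 0
    for i in range(0, len(argv), 2):
        xml_path, nt_path = argv[i], argv[i + 1]
        g1 = Graph()
        g1.parse(xml_path, format="xml")
        g2 = Graph()
        g2.parse(nt_path, format="nt")
        iso1, iso2 = to_isomorphic(g1), to_isomorphic(g2)
        if iso1 == iso2:
            print("OK %s" % xml_path)
        else:
            failures += 1
            _, in_first, in_second = graph_diff(iso1, iso2)
            print("FAIL %s" % xml_path)
            for t in sorted(in_first):
                print("  only-rdflib: %s %s %s" % t)
            for t in sorted(in_second):
                print("  only-other:  %s %s %s" % t)
    return 1 if failures else 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
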
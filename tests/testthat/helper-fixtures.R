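# Shared test helpers: random stores, a brute-force pattern oracle,
# N-Triples rendering for the rdflib cross-check, and python runners.

# Build a store holding `n` random triples over `nIris` IRI nodes and
# `nDocs` documents; returns the store plus an independent plain-data
# copy of what was inserted (post-dedup), for oracle filtering.
makeRandomStore <- function(n = 1000L, nIris = 120L, nDocs = 3L, seed = 1L,
                            indexes = defaultIndexConfig(),
                            withSubclass = TRUE) {
  set.seed(seed)
  st <- TripleStore(indexes = indexes)
  ids <- internIri(st, sprintf("http://example.org/ns%d#t%d",
                               seq_len(nIris) %% 7L, seq_len(nIris)))
  docs <- vapply(seq_len(nDocs), function(i)
    registerDocument(st, sprintf("mem:doc%d", i)), integer(1))
  s <- ids[sample.int(nIris, n, replace = TRUE)]
  p <- ids[sample.int(nIris, n, replace = TRUE)]
  if (withSubclass) {
    # make the benchmark workload predicate common
    p[sample.int(n, n %/% 5L)] <- vocabId("rdfs:subClassOf")
  }
  o <- ids[sample.int(nIris, n, replace = TRUE)]
  d <- docs[sample.int(nDocs, n, replace = TRUE)]
  addTriple(st, s, p, o, d)
  list(store = st, df = triples(st))
}

# Independent of the store internals: plain vectorized filter.
linearScanOracle <- function(df, s = NA, p = NA, o = NA, d = NA) {
  keep <- rep(TRUE, nrow(df))
  if (!is.na(s)) keep <- keep & df$subj == s
  if (!is.na(p)) keep <- keep & df$pred == p
  if (!is.na(o)) keep <- keep & df$obj == o
  if (!is.na(d)) keep <- keep & df$doc == d
  df[keep, , drop = FALSE]
}

tripleKey <- function(df) {
  sort(paste(df$subj, df$pred, df$obj, df$doc, sep = ","), method = "radix")
}

# All 16 wildcard/constrained combinations for a pattern drawn from a
# concrete triple (so most patterns have at least one match).
all16Patterns <- function(df, row) {
  base <- c(s = df$subj[row], p = df$pred[row], o = df$obj[row],
            d = df$doc[row])
  lapply(0:15, function(m) {
    on <- c(bitwAnd(m, 1L), bitwAnd(m, 2L), bitwAnd(m, 4L),
            bitwAnd(m, 8L)) > 0L
    out <- ifelse(on, base, NA_integer_)
    names(out) <- names(base)
    out
  })
}

# Deep snapshot of everything a store holds, for transactionality checks.
storeSnapshot <- function(st) {
  e <- st@ptr
  n <- e$nt
  list(
    ns = e$ns_pref,
    nodes = list(kind = e$node_kind, i1 = e$node_i1, i2 = e$node_i2,
                 c1 = e$node_c1, c2 = e$node_c2, pay = e$node_pay),
    docs = list(path = e$doc_path, onto = e$doc_onto, ver = e$doc_ver,
                blanks = e$doc_blank_n),
    triples = list(s = e$ts[seq_len(n)], p = e$tp[seq_len(n)],
                   o = e$to[seq_len(n)], d = e$td[seq_len(n)]),
    nodeMapKeys = sort(ls(e$node_map, all.names = TRUE)),
    nsMapKeys = sort(ls(e$ns_map, all.names = TRUE)),
    docMapKeys = sort(ls(e$doc_map, all.names = TRUE)),
    tripMapKeys = sort(ls(e$trip_map, all.names = TRUE))
  )
}

# Render a parseRdfXml() statement table as N-Triples for rdflib.
statementsToNTriples <- function(stmts) {
  escNT <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    x <- gsub("\"", "\\\"", x, fixed = TRUE)
    x <- gsub("\n", "\\n", x, fixed = TRUE)
    x <- gsub("\r", "\\r", x, fixed = TRUE)
    gsub("\t", "\\t", x, fixed = TRUE)
  }
  labels <- unique(c(stmts$s[stmts$sKind == "blank"],
                     stmts$o[stmts$oKind == "blank"]))
  blankName <- function(l) paste0("_:b", match(l, labels))
  term <- function(v, kind, dt = NA, lang = "") {
    if (kind == "iri") return(paste0("<", v, ">"))
    if (kind == "blank") return(blankName(v))
    out <- paste0("\"", escNT(v), "\"")
    if (!is.na(dt)) {
      # rdflib treats rdf:XMLLiteral specially; plain types carry no suffix
      paste0(out, "^^<", dt, ">")
    } else if (nzchar(lang)) {
      paste0(out, "@", lang)
    } else {
      out
    }
  }
  vapply(seq_len(nrow(stmts)), function(i) {
    paste(term(stmts$s[i], stmts$sKind[i]),
          paste0("<", stmts$p[i], ">"),
          term(stmts$o[i], stmts$oKind[i], stmts$oDatatype[i],
               stmts$oLang[i]),
          ".")
  }, character(1))
}

oraclePath <- function(name) {
  p <- system.file("oracle", name, package = "owlstore")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "oracle", name)
  p
}

runPython <- function(script, args) {
  out <- suppressWarnings(system2("python", shQuote(c(script, args)),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-written document exercising the expression and assertion subset.
richOntologyXml <- function() {
  paste0('<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#"
         xmlns:xsd="http://www.w3.org/2001/XMLSchema#"
         xmlns:z="http://example.org/zoo#">
  <owl:Ontology rdf:about="http://example.org/zoo"/>
  <owl:Class rdf:about="http://example.org/zoo#Animal"/>
  <owl:Class rdf:about="http://example.org/zoo#Dog"/>
  <owl:Class rdf:about="http://example.org/zoo#Cat"/>
  <owl:Class rdf:about="http://example.org/zoo#Pet"/>
  <owl:ObjectProperty rdf:about="http://example.org/zoo#hasOwner"/>
  <owl:DatatypeProperty rdf:about="http://example.org/zoo#age"/>
  <owl:AnnotationProperty rdf:about="http://example.org/zoo#curator"/>
  <owl:NamedIndividual rdf:about="http://example.org/zoo#rex"/>
  <owl:NamedIndividual rdf:about="http://example.org/zoo#alice"/>
  <rdf:Description rdf:about="http://example.org/zoo#Dog">
    <rdfs:subClassOf rdf:resource="http://example.org/zoo#Animal"/>
    <owl:disjointWith rdf:resource="http://example.org/zoo#Cat"/>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/zoo#Pet">
    <owl:equivalentClass>
      <owl:Class>
        <owl:intersectionOf rdf:parseType="Collection">
          <owl:Class rdf:about="http://example.org/zoo#Animal"/>
          <owl:Restriction>
            <owl:onProperty rdf:resource="http://example.org/zoo#hasOwner"/>
            <owl:someValuesFrom rdf:resource="http://example.org/zoo#Animal"/>
          </owl:Restriction>
        </owl:intersectionOf>
      </owl:Class>
    </owl:equivalentClass>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/zoo#Dog">
    <rdfs:subClassOf>
      <owl:Restriction>
        <owl:onProperty rdf:resource="http://example.org/zoo#hasOwner"/>
        <owl:maxCardinality
          rdf:datatype="http://www.w3.org/2001/XMLSchema#nonNegativeInteger"
          >2</owl:maxCardinality>
      </owl:Restriction>
    </rdfs:subClassOf>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/zoo#hasOwner">
    <rdf:type rdf:resource="http://www.w3.org/2002/07/owl#FunctionalProperty"/>
    <rdfs:domain rdf:resource="http://example.org/zoo#Animal"/>
    <rdfs:range rdf:resource="http://example.org/zoo#Animal"/>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/zoo#age">
    <rdfs:range rdf:resource="http://www.w3.org/2001/XMLSchema#int"/>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/zoo#rex">
    <rdf:type rdf:resource="http://example.org/zoo#Dog"/>
    <z:hasOwner rdf:resource="http://example.org/zoo#alice"/>
    <z:age rdf:datatype="http://www.w3.org/2001/XMLSchema#int">007</z:age>
    <rdfs:label xml:lang="en">Rex</rdfs:label>
  </rdf:Description>
</rdf:RDF>')
}
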
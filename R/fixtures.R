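## Synthetic ontology documents and query workloads.
##
## The generator produces small RDF/XML ontologies whose expected statement
## multiset, expected axiom multiset and expected blank-node count are
## known in closed form, so the parser, the loader and the axiom mapper can
## be tested round-trip without downloading anything. Deliberately broken
## variants fail at a named stage of the pipeline.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Describe a synthetic ontology document
#'
#' @param nClasses,nObjectProperties,nSubclassLinks,nRestrictions,nAnnotations,nImports
#'   entity and axiom counts. Subclass links are distinct ordered pairs of
#'   distinct classes, so `nSubclassLinks <= nClasses * (nClasses - 1)`.
#'   Restrictions are existential (`someValuesFrom`) superclasses and
#'   require at least one object property and two classes.
#' @param errorInjection `"none"` for a valid document, or one of
#'   `"xml"` (truncated document), `"rdf"` (duplicate `rdf:ID`),
#'   `"owl_header"` (second `owl:Ontology` header, fails at load),
#'   `"owl_undeclared"` (triple with an undeclared predicate, loads but
#'   fails axiom mapping), `"owl_misspelled"` (misspelled standard OWL
#'   term, loads but fails axiom mapping).
#' @param seed integer; generation is deterministic under it.
#' @return an `ontologySpec` object for [generateOntologyDocument()].
#' @export
ontologySpec <- function(nClasses = 10L, nObjectProperties = 2L,
                         nSubclassLinks = 10L, nRestrictions = 0L,
                         nAnnotations = 0L, nImports = 0L,
                         errorInjection = "none", seed = 1L) {
  spec <- list(nClasses = as.integer(nClasses),
               nObjectProperties = as.integer(nObjectProperties),
               nSubclassLinks = as.integer(nSubclassLinks),
               nRestrictions = as.integer(nRestrictions),
               nAnnotations = as.integer(nAnnotations),
               nImports = as.integer(nImports),
               errorInjection = errorInjection,
               seed = as.integer(seed))
  counts <- unlist(spec[1:6])
  if (any(is.na(counts)) || any(counts < 0L)) {
    stopValueError("ontologySpec counts must be non-negative integers")
  }
  if (spec$nSubclassLinks > spec$nClasses * max(spec$nClasses - 1L, 0L)) {
    stopValueError("nSubclassLinks exceeds the number of distinct class pairs")
  }
  if (spec$nRestrictions > 0L &&
      (spec$nObjectProperties < 1L || spec$nClasses < 2L)) {
    stopValueError("restrictions need at least one object property and two classes")
  }
  ok <- c("none", "xml", "rdf", "owl_header", "owl_undeclared",
          "owl_misspelled")
  if (!errorInjection %in% ok) {
    stopValueError(sprintf("unknown errorInjection '%s'", errorInjection))
  }
  structure(spec, class = "ontologySpec")
}

#' @export
print.ontologySpec <- function(x, ...) {
  cat(sprintf(
    "ontologySpec: %d classes, %d obj-properties, %d links, %d restrictions, %d annotations, %d imports; error=%s; seed=%d\n",
    x$nClasses, x$nObjectProperties, x$nSubclassLinks, x$nRestrictions,
    x$nAnnotations, x$nImports, x$errorInjection, x$seed))
  invisible(x)
}

.stmtRow <- function(s, sk, p, o, ok, dt = NA_character_, lang = "") {
  data.frame(s = s, sKind = sk, p = p, o = o, oKind = ok, oDatatype = dt,
             oLang = lang, stringsAsFactors = FALSE)
}

#' Generate a synthetic ontology document
#'
#' Deterministic under the spec's seed: the same spec always yields
#' byte-identical RDF/XML. For valid specs the expected statement multiset
#' (with the blank labels the parser will assign), the expected axiom
#' multiset (as canonical full-IRI strings, see [axiomStrings()]) and the
#' expected counts are returned alongside the document; for error-injected
#' specs the expected failure stage is returned instead of expectations.
#'
#' @param spec an [ontologySpec()].
#' @param ontologyIri ontology IRI of the document.
#' @param importIris IRIs placed in `owl:imports` (length `nImports`).
#' @return a list with elements `xml` (the document text), `statements`
#'   (data.frame as from [parseRdfXml()], or `NULL` for `"xml"`/`"rdf"`
#'   injections), `axioms` (character vector, or `NULL` when the document
#'   cannot be mapped), `expectedError` (`NULL`, or a list with `stage`
#'   and `class`), `counts` (statements, axioms, blanks), `ontologyIri`,
#'   `importIris`.
#' @export
generateOntologyDocument <- function(spec,
                                     ontologyIri = sprintf(
                                       "http://example.org/onto%04d",
                                       spec$seed),
                                     importIris = if (spec$nImports > 0L)
                                       sprintf("%s/imp%d", ontologyIri,
                                               seq_len(spec$nImports))
                                     else character(0)) {
  stopifnot(inherits(spec, "ontologySpec"))
  if (length(importIris) != spec$nImports) {
    stopValueError("importIris must have length nImports")
  }
  .withSeed(spec$seed, .generateDoc(spec, ontologyIri, importIris))
}

.generateDoc <- function(spec, ontologyIri, importIris) {
  nC <- spec$nClasses
  nP <- spec$nObjectProperties
  cls <- sprintf("%s#C%d", ontologyIri, seq_len(nC))
  prp <- sprintf("%s#p%d", ontologyIri, seq_len(nP))
  rdfsSub <- paste0(.NS_RDFS, "subClassOf")
  rdfsLabel <- paste0(.NS_RDFS, "label")
  typeIri <- paste0(.NS_RDF, "type")

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<rdf:RDF xmlns:rdf=\"%s\" xmlns:rdfs=\"%s\" ",
                   "xmlns:owl=\"%s\" xmlns:xsd=\"%s\" xmlns:ex=\"%s#\" ",
                   "xml:base=\"%s\">"),
            .NS_RDF, .NS_RDFS, .NS_OWL, .NS_XSD, ontologyIri, ontologyIri)
  )
  stmts <- list()
  addSt <- function(df) stmts[[length(stmts) + 1L]] <<- df
  axioms <- character(0)
  addAx <- function(a) axioms <<- c(axioms, a)

  ## header
  if (spec$nImports > 0L) {
    lines <- c(lines,
               sprintf("  <owl:Ontology rdf:about=\"%s\">", ontologyIri),
               sprintf("    <owl:imports rdf:resource=\"%s\"/>", importIris),
               "  </owl:Ontology>")
  } else {
    lines <- c(lines, sprintf("  <owl:Ontology rdf:about=\"%s\"/>", ontologyIri))
  }
  addSt(.stmtRow(ontologyIri, "iri", typeIri, paste0(.NS_OWL, "Ontology"),
                 "iri"))
  for (imp in importIris) {
    addSt(.stmtRow(ontologyIri, "iri", paste0(.NS_OWL, "imports"), imp, "iri"))
    addAx(sprintf("Import(<%s>)", imp))
  }
  addAx(sprintf("Ontology(<%s>)", ontologyIri))

  ## declarations
  for (ci in cls) {
    lines <- c(lines, sprintf("  <owl:Class rdf:about=\"%s\"/>", ci))
    addSt(.stmtRow(ci, "iri", typeIri, paste0(.NS_OWL, "Class"), "iri"))
    addAx(sprintf("Declaration(Class(<%s>))", ci))
  }
  for (pi in prp) {
    lines <- c(lines, sprintf("  <owl:ObjectProperty rdf:about=\"%s\"/>", pi))
    addSt(.stmtRow(pi, "iri", typeIri, paste0(.NS_OWL, "ObjectProperty"),
                   "iri"))
    addAx(sprintf("Declaration(ObjectProperty(<%s>))", pi))
  }

  ## named subclass links: distinct ordered pairs of distinct classes
  if (spec$nSubclassLinks > 0L) {
    pairIdx <- sample.int(nC * (nC - 1L), spec$nSubclassLinks)
    a <- (pairIdx - 1L) %/% (nC - 1L) + 1L
    b <- (pairIdx - 1L) %% (nC - 1L) + 1L
    b <- ifelse(b >= a, b + 1L, b)
    for (k in seq_len(spec$nSubclassLinks)) {
      lines <- c(lines,
                 sprintf("  <rdf:Description rdf:about=\"%s\">", cls[a[k]]),
                 sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>", cls[b[k]]),
                 "  </rdf:Description>")
      addSt(.stmtRow(cls[a[k]], "iri", rdfsSub, cls[b[k]], "iri"))
      addAx(sprintf("SubClassOf(<%s> <%s>)", cls[a[k]], cls[b[k]]))
    }
  }

  ## existential restrictions as anonymous superclasses (one blank each)
  if (spec$nRestrictions > 0L) {
    ri <- sample.int(nC, spec$nRestrictions, replace = TRUE)
    rp <- sample.int(nP, spec$nRestrictions, replace = TRUE)
    rk <- sample.int(nC, spec$nRestrictions, replace = TRUE)
    for (k in seq_len(spec$nRestrictions)) {
      blank <- sprintf(".g%d", k)  # parser assigns generated labels in order
      lines <- c(lines,
                 sprintf("  <rdf:Description rdf:about=\"%s\">", cls[ri[k]]),
                 "    <rdfs:subClassOf>",
                 "      <owl:Restriction>",
                 sprintf("        <owl:onProperty rdf:resource=\"%s\"/>", prp[rp[k]]),
                 sprintf("        <owl:someValuesFrom rdf:resource=\"%s\"/>", cls[rk[k]]),
                 "      </owl:Restriction>",
                 "    </rdfs:subClassOf>",
                 "  </rdf:Description>")
      addSt(.stmtRow(blank, "blank", typeIri, paste0(.NS_OWL, "Restriction"),
                     "iri"))
      addSt(.stmtRow(blank, "blank", paste0(.NS_OWL, "onProperty"),
                     prp[rp[k]], "iri"))
      addSt(.stmtRow(blank, "blank", paste0(.NS_OWL, "someValuesFrom"),
                     cls[rk[k]], "iri"))
      addSt(.stmtRow(cls[ri[k]], "iri", rdfsSub, blank, "blank"))
      addAx(sprintf("SubClassOf(<%s> ObjectSomeValuesFrom(<%s> <%s>))",
                    cls[ri[k]], prp[rp[k]], cls[rk[k]]))
    }
  }

  ## rdfs:label annotations with unique texts
  if (spec$nAnnotations > 0L) {
    ai <- sample.int(nC, spec$nAnnotations, replace = TRUE)
    for (k in seq_len(spec$nAnnotations)) {
      txt <- sprintf("label %d", k)
      lines <- c(lines,
                 sprintf("  <rdf:Description rdf:about=\"%s\">", cls[ai[k]]),
                 sprintf("    <rdfs:label xml:lang=\"en\">%s</rdfs:label>", txt),
                 "  </rdf:Description>")
      addSt(.stmtRow(cls[ai[k]], "iri", rdfsLabel, txt, "lit", lang = "en"))
      addAx(sprintf("AnnotationAssertion(<%s> <%s> \"%s\"@en)",
                    rdfsLabel, cls[ai[k]], txt))
    }
  }

  expectedError <- NULL
  err <- spec$errorInjection
  if (err == "rdf") {
    lines <- c(lines,
               "  <owl:Class rdf:ID=\"Duplicated\"/>",
               "  <owl:Class rdf:ID=\"Duplicated\"/>")
    expectedError <- list(stage = "rdf", class = "owlstore_load_error")
  } else if (err == "owl_header") {
    lines <- c(lines,
               sprintf("  <owl:Ontology rdf:about=\"%s/second\"/>", ontologyIri))
    expectedError <- list(stage = "owl", class = "owlstore_load_error")
  } else if (err == "owl_undeclared") {
    lines <- c(lines,
               sprintf("  <rdf:Description rdf:about=\"%s\">", cls[1]),
               sprintf("    <ex:partOf rdf:resource=\"%s\"/>",
                       cls[min(2L, nC)]),
               "  </rdf:Description>")
    addSt(.stmtRow(cls[1], "iri", sprintf("%s#partOf", ontologyIri),
                   cls[min(2L, nC)], "iri"))
    expectedError <- list(stage = "owl",
                          class = "owlstore_undeclared_predicate_error")
  } else if (err == "owl_misspelled") {
    lines <- c(lines,
               sprintf("  <owl:Classs rdf:about=\"%s#Misspelled\"/>",
                       ontologyIri))
    addSt(.stmtRow(sprintf("%s#Misspelled", ontologyIri), "iri", typeIri,
                   paste0(.NS_OWL, "Classs"), "iri"))
    expectedError <- list(stage = "owl",
                          class = "owlstore_misspelled_term_error")
  }
  lines <- c(lines, "</rdf:RDF>")
  xml <- paste(lines, collapse = "\n")
  if (err == "xml") {
    xml <- substr(xml, 1L, nchar(xml) - 40L)
    expectedError <- list(stage = "xml", class = "owlstore_load_error")
  }

  statements <- if (err %in% c("xml", "rdf", "owl_header")) NULL else
    do.call(rbind, stmts)
  axOut <- if (err == "none") axioms else NULL
  list(
    xml = xml,
    statements = statements,
    axioms = axOut,
    expectedError = expectedError,
    counts = list(
      statements = if (is.null(statements)) NA_integer_ else nrow(statements),
      axioms = if (is.null(axOut)) NA_integer_ else length(axOut),
      blanks = spec$nRestrictions
    ),
    ontologyIri = ontologyIri,
    importIris = importIris,
    spec = spec
  )
}

## ---- query workloads ------------------------------------------------------

#' Generate a triple-pattern query workload
#'
#' `type = "subclass"` reproduces the classic triple-search benchmark
#' pattern: a subject chosen uniformly at random among the store's triple
#' subjects, combined with the fixed predicate `rdfs:subClassOf`.
#' `type = "all16"` draws patterns uniformly over all 16 combinations of
#' constrained/wildcard positions, with constrained values sampled from the
#' IDs actually occurring in that position.
#'
#' @param store a [TripleStore] with at least one triple.
#' @param nQueries number of patterns.
#' @param seed RNG seed; the workload is reproducible under it.
#' @param type `"subclass"` or `"all16"`.
#' @return a data.frame with integer columns `s`, `p`, `o`, `d`; `NA`
#'   means wildcard.
#' @export
generateWorkload <- function(store, nQueries, seed = 1L,
                             type = c("subclass", "all16")) {
  type <- match.arg(type)
  e <- store@ptr
  n <- e$nt
  if (n < 1L) stopValueError("workload generation needs a non-empty store")
  .withSeed(seed, {
    if (type == "subclass") {
      subjects <- unique(e$ts[seq_len(n)])
      data.frame(s = subjects[sample.int(length(subjects), nQueries,
                                         replace = TRUE)],
                 p = rep(vocabId("rdfs:subClassOf"), nQueries),
                 o = NA_integer_, d = NA_integer_)
    } else {
      pools <- list(s = unique(e$ts[seq_len(n)]), p = unique(e$tp[seq_len(n)]),
                    o = unique(e$to[seq_len(n)]), d = unique(e$td[seq_len(n)]))
      combo <- sample.int(16L, nQueries, replace = TRUE) - 1L
      draw <- function(pool, on) {
        v <- pool[sample.int(length(pool), nQueries, replace = TRUE)]
        ifelse(on, v, NA_integer_)
      }
      data.frame(s = draw(pools$s, bitwAnd(combo, 1L) > 0L),
                 p = draw(pools$p, bitwAnd(combo, 2L) > 0L),
                 o = draw(pools$o, bitwAnd(combo, 4L) > 0L),
                 d = draw(pools$d, bitwAnd(combo, 8L) > 0L))
    }
  })
}

## ---- index-configuration study --------------------------------------------

#' Compare index configurations by comparison counts
#'
#' Re-indexes the store's contents under each configuration, answers the
#' whole workload, and reports the total number of element comparisons
#' each configuration incurred (binary-search probes plus residual-filter
#' tests). All configurations are asserted to return identical result
#' multisets; the counts isolate the work an index layout saves,
#' independent of hardware and clock.
#'
#' @param store a [TripleStore] holding the triples to study.
#' @param configs character vector; each entry is an index layout string
#'   (see [parseIndexSpec()]), or `"scan"` for the indexless linear-scan
#'   baseline.
#' @param workload a data.frame from [generateWorkload()].
#' @return a data.frame with columns `config`, `comparisons`, `results`
#'   (total matches over the workload).
#' @export
indexStudy <- function(store, configs, workload) {
  if (!length(configs)) stopConfigError("indexStudy needs at least one config")
  out <- data.frame(config = character(0), comparisons = numeric(0),
                    results = numeric(0), stringsAsFactors = FALSE)
  sig0 <- NULL
  for (cfg in configs) {
    force.scan <- identical(cfg, "scan")
    st2 <- .cloneStore(store, if (force.scan) "s:pod" else cfg)
    e2 <- st2@ptr
    counter <- new.env(parent = emptyenv())
    counter$n <- 0
    hits <- vector("list", nrow(workload))
    for (q in seq_len(nrow(workload))) {
      pat <- list(s = workload$s[q], p = workload$p[q],
                  o = workload$o[q], d = workload$d[q])
      rows <- .findRows(e2, pat, counter = counter,
                        forceScan = force.scan)$rows
      hits[[q]] <- paste(q, e2$ts[rows], e2$tp[rows], e2$to[rows],
                         e2$td[rows], sep = ",")
    }
    sig <- sort(as.character(unlist(hits)), method = "radix")
    if (is.null(sig0)) {
      sig0 <- sig
    } else if (!identical(sig, sig0)) {
      stop("internal error: index configurations disagree on query results")
    }
    out <- rbind(out, data.frame(config = cfg, comparisons = counter$n,
                                 results = length(sig),
                                 stringsAsFactors = FALSE))
  }
  out
}
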
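## Translation of stored RDF triples into OWL 2 axioms.
##
## Two-pass, strict translation following the W3C RDF-graph mapping:
## declarations are collected first, then axiom triples are interpreted.
## Every triple in scope must be consumed exactly once — as an axiom
## trigger, as part of an expression or list structure, as a declaration,
## or as an annotation. Any leftover, any undeclared predicate, any IRI in
## a standard namespace that is not a standard term ("misspelling"), and
## any recognized-but-unsupported OWL construct aborts the whole
## translation with an informative error; no partial axiom list is ever
## returned.

.DECL_KINDS <- function() c(
  stats::setNames("Class", vocabId("owl:Class")),
  stats::setNames("ObjectProperty", vocabId("owl:ObjectProperty")),
  stats::setNames("DataProperty", vocabId("owl:DatatypeProperty")),
  stats::setNames("AnnotationProperty", vocabId("owl:AnnotationProperty")),
  stats::setNames("NamedIndividual", vocabId("owl:NamedIndividual")),
  stats::setNames("Datatype", vocabId("rdfs:Datatype"))
)

.BUILTIN_ANNOTATION_QN <- c(
  "rdfs:label", "rdfs:comment", "rdfs:seeAlso", "rdfs:isDefinedBy",
  "owl:deprecated", "owl:versionInfo", "owl:backwardCompatibleWith",
  "owl:incompatibleWith", "owl:priorVersion"
)

.UNSUPPORTED_PRED_QN <- c(
  "owl:propertyChainAxiom", "owl:hasKey", "owl:disjointUnionOf",
  "owl:inverseOf", "owl:equivalentProperty", "owl:propertyDisjointWith",
  "owl:sameAs", "owl:differentFrom", "owl:distinctMembers", "owl:members",
  "owl:sourceIndividual", "owl:assertionProperty", "owl:targetIndividual",
  "owl:targetValue", "owl:onDatatype", "owl:withRestrictions",
  "owl:datatypeComplementOf", "owl:hasSelf"
)

.UNSUPPORTED_TYPE_QN <- c(
  "owl:AllDifferent", "owl:AllDisjointClasses", "owl:AllDisjointProperties",
  "owl:NegativePropertyAssertion", "owl:DeprecatedClass",
  "owl:DeprecatedProperty", "rdf:Bag", "rdf:Seq", "rdf:Alt", "rdf:Property"
)

.CHARACTERISTIC_QN <- c(
  "owl:FunctionalProperty", "owl:InverseFunctionalProperty",
  "owl:TransitiveProperty", "owl:SymmetricProperty"
)

## predicates that only occur inside blank-node expression / list structures
.STRUCTURE_PRED_QN <- c(
  "owl:intersectionOf", "owl:unionOf", "owl:complementOf", "owl:oneOf",
  "owl:onProperty", "owl:someValuesFrom", "owl:allValuesFrom",
  "owl:hasValue", "owl:minCardinality", "owl:maxCardinality",
  "owl:cardinality", "owl:minQualifiedCardinality",
  "owl:maxQualifiedCardinality", "owl:qualifiedCardinality",
  "owl:onClass", "owl:onDataRange", "rdf:first", "rdf:rest"
)

.qnIds <- function(qns) vapply(qns, vocabId, integer(1), USE.NAMES = FALSE)

## ---- declarations ---------------------------------------------------------

.newDecls <- function() {
  map <- new.env(parent = emptyenv())
  obj <- structure(list(map = map), class = "owlDeclarations")
  obj
}

#' @export
print.owlDeclarations <- function(x, ...) {
  cat(sprintf("OWL declarations for %d entities\n",
              length(ls(x$map, all.names = TRUE))))
  invisible(x)
}

.declSet <- function(decls, id, kind) {
  key <- as.character(id)
  old <- get0(key, envir = decls$map, inherits = FALSE)
  if (!is.null(old) && old != kind) {
    conflict <- setequal(c(old, kind), c("ObjectProperty", "DataProperty"))
    if (conflict) {
      stopMappingError(
        sprintf("entity %d is declared both ObjectProperty and DataProperty",
                id),
        class = "owlstore_decl_conflict_error")
    }
    ## punning (e.g. Class + NamedIndividual) is allowed; keep both kinds
    assign(key, c(old, kind), envir = decls$map)
    return(invisible(NULL))
  }
  assign(key, kind, envir = decls$map)
  invisible(NULL)
}

#' Declared kind(s) of an entity
#' @param decls declarations from [collectDeclarations()].
#' @param id an integer NodeId.
#' @return character vector of kinds (`"Class"`, `"ObjectProperty"`,
#'   `"DataProperty"`, `"AnnotationProperty"`, `"NamedIndividual"`,
#'   `"Datatype"`), or `NULL` when undeclared.
#' @export
declKind <- function(decls, id) {
  get0(as.character(id), envir = decls$map, inherits = FALSE)
}

.hasKind <- function(decls, id, kind) kind %in% declKind(decls, id)

.predeclareBuiltins <- function(decls) {
  for (qn in c("owl:Thing", "owl:Nothing")) {
    .declSet(decls, vocabId(qn), "Class")
  }
  for (t in .VOCAB_TERMS$xsd) {
    iri <- paste0(.NS_XSD, t)
    id <- get0(iri, envir = .vocabEnv, inherits = FALSE)
    if (!is.null(id)) .declSet(decls, id, "Datatype")
  }
  for (qn in c("rdfs:Literal", "rdf:XMLLiteral", "rdf:PlainLiteral",
               "rdf:langString", "rdf:HTML", "owl:rational", "owl:real")) {
    .declSet(decls, vocabId(qn), "Datatype")
  }
  .declSet(decls, vocabId("owl:topObjectProperty"), "ObjectProperty")
  .declSet(decls, vocabId("owl:bottomObjectProperty"), "ObjectProperty")
  .declSet(decls, vocabId("owl:topDataProperty"), "DataProperty")
  .declSet(decls, vocabId("owl:bottomDataProperty"), "DataProperty")
  for (qn in .BUILTIN_ANNOTATION_QN) {
    .declSet(decls, vocabId(qn), "AnnotationProperty")
  }
  invisible(decls)
}

#' Collect entity declarations from triples
#'
#' Records every `(x, rdf:type, K)` with `K` a declarable kind
#' (`owl:Class`, `owl:ObjectProperty`, `owl:DatatypeProperty`,
#' `owl:AnnotationProperty`, `owl:NamedIndividual`, `rdfs:Datatype`) and a
#' named subject. Built-in vocabulary (standard datatypes, `owl:Thing`,
#' the top/bottom properties, the built-in annotation properties) is
#' pre-declared. An entity declared both object and data property is a
#' conflict and aborts with an error.
#'
#' @param store a [TripleStore].
#' @param doc optional DocId restricting the triples considered.
#' @return an opaque declarations object; query it with [declKind()].
#' @export
collectDeclarations <- function(store, doc = NULL) {
  e <- store@ptr
  n <- e$nt
  rows <- seq_len(n)
  if (!is.null(doc)) rows <- rows[e$td[rows] == as.integer(doc)]
  decls <- .predeclareBuiltins(.newDecls())
  declKinds <- .DECL_KINDS()
  typeId <- vocabId("rdf:type")
  sel <- rows[e$tp[rows] == typeId &
                e$to[rows] %in% as.integer(names(declKinds))]
  for (r in sel) {
    s <- e$ts[r]
    if (e$node_kind[s] != .KIND_IRI) next
    .declSet(decls, s, unname(declKinds[as.character(e$to[r])]))
  }
  decls
}

## ---- mapping context ------------------------------------------------------

.newMapCtx <- function(store, doc = NULL) {
  e <- store@ptr
  rows <- seq_len(e$nt)
  if (!is.null(doc)) rows <- rows[e$td[rows] == as.integer(doc)]
  ctx <- new.env(parent = emptyenv())
  ctx$store <- store
  ctx$e <- e
  ctx$rows <- rows
  ctx$s <- e$ts[rows]
  ctx$p <- e$tp[rows]
  ctx$o <- e$to[rows]
  ctx$consumed <- logical(length(rows))
  ctx$decls <- NULL
  ctx$memo <- new.env(parent = emptyenv())
  ctx$inprog <- new.env(parent = emptyenv())
  ctx$axAnn <- new.env(parent = emptyenv())
  ctx
}

.rw <- function(ctx, s = NA, p = NA, o = NA) {
  keep <- rep(TRUE, length(ctx$rows))
  if (!is.na(s)) keep <- keep & ctx$s == s
  if (!is.na(p)) keep <- keep & ctx$p == p
  if (!is.na(o)) keep <- keep & ctx$o == o
  which(keep)
}

.consume <- function(ctx, pos) {
  ctx$consumed[pos] <- TRUE
  invisible(NULL)
}

.nodeLabel <- function(e, id) {
  kind <- e$node_kind[id]
  if (kind == .KIND_IRI) {
    paste0("<", .iriString(e, id), ">")
  } else if (kind == .KIND_LIT) {
    paste0("\"", e$node_c1[id], "\"")
  } else {
    paste0("_:d", e$node_i1[id], "_", e$node_i2[id])
  }
}

.isBlank <- function(ctx, id) ctx$e$node_kind[id] == .KIND_BLANK
.isIriNode <- function(ctx, id) ctx$e$node_kind[id] == .KIND_IRI
.isLiteral <- function(ctx, id) ctx$e$node_kind[id] == .KIND_LIT

## ---- misspelled standard terms --------------------------------------------

.checkSpelling <- function(ctx) {
  e <- ctx$e
  ids <- unique(c(ctx$s, ctx$p, ctx$o))
  ids <- ids[e$node_kind[ids] == .KIND_IRI]
  ids <- ids[ids > .vocabCount()]  # constants are the standard terms
  for (id in ids) {
    nsIri <- e$ns_pref[e$node_i1[id]]
    if (.isStdNamespace(nsIri) && !.isStdTerm(nsIri, e$node_c1[id])) {
      stopMappingError(
        sprintf("misspelled standard term: %s is not part of the %s vocabulary",
                .nodeLabel(e, id), nsIri),
        class = "owlstore_misspelled_term_error")
    }
  }
  invisible(NULL)
}

## ---- RDF lists ------------------------------------------------------------

.parseListCtx <- function(ctx, head) {
  nilId <- vocabId("rdf:nil")
  firstId <- vocabId("rdf:first")
  restId <- vocabId("rdf:rest")
  members <- integer(0)
  cell <- head
  seen <- integer(0)
  while (cell != nilId) {
    if (cell %in% seen) {
      stopMappingError(sprintf("rdf list contains a cycle at %s",
                               .nodeLabel(ctx$e, cell)))
    }
    seen <- c(seen, cell)
    fr <- .rw(ctx, s = cell, p = firstId)
    rr <- .rw(ctx, s = cell, p = restId)
    if (length(fr) != 1L || length(rr) != 1L) {
      stopMappingError(sprintf(
        "malformed rdf list node %s: %d rdf:first and %d rdf:rest triples",
        .nodeLabel(ctx$e, cell), length(fr), length(rr)))
    }
    if (ctx$consumed[fr] || ctx$consumed[rr]) {
      stopMappingError(sprintf("rdf list node %s is shared between lists",
                               .nodeLabel(ctx$e, cell)))
    }
    .consume(ctx, c(fr, rr))
    members <- c(members, ctx$o[fr])
    cell <- ctx$o[rr]
  }
  members
}

#' Walk an RDF collection
#'
#' Follows `rdf:first`/`rdf:rest` links from `head` to `rdf:nil` and
#' returns the member NodeIds in order. Missing or duplicated links,
#' branching, shared tails and cycles are malformed and raise a mapping
#' error naming the offending node.
#'
#' @param store a [TripleStore].
#' @param head NodeId of the list head (possibly `rdf:nil`).
#' @param doc optional DocId restricting the triples considered.
#' @return integer vector of member NodeIds.
#' @export
parseRdfList <- function(store, head, doc = NULL) {
  ctx <- .newMapCtx(store, doc)
  .parseListCtx(ctx, as.integer(head))
}

## ---- class expressions ----------------------------------------------------

.namedClassExpr <- function(ctx, id) {
  if (!.hasKind(ctx$decls, id, "Class")) {
    stopMappingError(sprintf("undeclared class %s", .nodeLabel(ctx$e, id)))
  }
  list(type = "named", id = id)
}

.cardinalityValue <- function(ctx, id) {
  e <- ctx$e
  if (e$node_kind[id] != .KIND_LIT) {
    stopMappingError(sprintf("cardinality value %s is not a literal",
                             .nodeLabel(e, id)))
  }
  v <- e$node_pay[[id]]
  if (!is.numeric(v) || is.na(v) || v < 0 || v != floor(v)) {
    stopMappingError(sprintf(
      "cardinality literal \"%s\" is not a non-negative integer", e$node_c1[id]))
  }
  as.integer(v)
}

.datatypeRef <- function(ctx, id) {
  if (!.isIriNode(ctx, id) || !.hasKind(ctx$decls, id, "Datatype")) {
    stopMappingError(sprintf("%s is not a known datatype",
                             .nodeLabel(ctx$e, id)))
  }
  id
}

.classExpr <- function(ctx, id) {
  e <- ctx$e
  if (.isLiteral(ctx, id)) {
    stopMappingError(sprintf("literal %s cannot be a class expression",
                             .nodeLabel(e, id)))
  }
  if (.isIriNode(ctx, id)) return(.namedClassExpr(ctx, id))

  key <- as.character(id)
  memo <- get0(key, envir = ctx$memo, inherits = FALSE)
  if (!is.null(memo)) return(memo)
  if (!is.null(get0(key, envir = ctx$inprog, inherits = FALSE))) {
    stopMappingError(sprintf("class expression at %s is cyclic",
                             .nodeLabel(e, id)))
  }
  assign(key, TRUE, envir = ctx$inprog)

  here <- .rw(ctx, s = id)
  here <- here[!ctx$consumed[here]]
  preds <- ctx$p[here]
  predOf <- function(qn) here[preds == vocabId(qn)]
  take <- function(pos) .consume(ctx, pos)

  typeRows <- predOf("rdf:type")
  isRestriction <- any(ctx$o[typeRows] == vocabId("owl:Restriction"))

  expr <- NULL
  used <- integer(0)

  if (isRestriction) {
    restrTypeRow <- typeRows[ctx$o[typeRows] == vocabId("owl:Restriction")]
    used <- c(used, restrTypeRow)
    onP <- predOf("owl:onProperty")
    if (length(onP) != 1L) {
      stopMappingError(sprintf(
        "restriction at %s must have exactly one owl:onProperty (found %d)",
        .nodeLabel(e, id), length(onP)))
    }
    used <- c(used, onP)
    prop <- ctx$o[onP]
    propKind <-
      if (.hasKind(ctx$decls, prop, "ObjectProperty")) "object"
      else if (.hasKind(ctx$decls, prop, "DataProperty")) "data"
      else stopMappingError(sprintf(
        "restriction at %s: owl:onProperty value %s is not a declared property",
        .nodeLabel(e, id), .nodeLabel(e, prop)))

    fillerKeys <- c(some = "owl:someValuesFrom", only = "owl:allValuesFrom",
                    value = "owl:hasValue",
                    min = "owl:minCardinality", max = "owl:maxCardinality",
                    exactly = "owl:cardinality",
                    min = "owl:minQualifiedCardinality",
                    max = "owl:maxQualifiedCardinality",
                    exactly = "owl:qualifiedCardinality")
    hits <- lapply(fillerKeys, predOf)
    nHit <- vapply(hits, length, integer(1))
    if (sum(nHit) != 1L) {
      stopMappingError(sprintf(
        "restriction at %s must have exactly one filler key (found %d)",
        .nodeLabel(e, id), sum(nHit)))
    }
    which1 <- which(nHit == 1L)
    row1 <- hits[[which1]]
    used <- c(used, row1)
    kind <- names(fillerKeys)[which1]
    qualified <- fillerKeys[which1] %in% c("owl:minQualifiedCardinality",
                                           "owl:maxQualifiedCardinality",
                                           "owl:qualifiedCardinality")
    val <- ctx$o[row1]

    filler <- NULL
    nCard <- NULL
    if (kind %in% c("some", "only")) {
      filler <- if (propKind == "object") .classExpr(ctx, val)
                else .datatypeRef(ctx, val)
    } else if (kind == "value") {
      if (propKind == "data") {
        if (!.isLiteral(ctx, val)) {
          stopMappingError(sprintf(
            "data restriction at %s: owl:hasValue must be a literal",
            .nodeLabel(e, id)))
        }
      } else if (.isLiteral(ctx, val)) {
        stopMappingError(sprintf(
          "object restriction at %s: owl:hasValue must be an individual",
          .nodeLabel(e, id)))
      }
      filler <- val
    } else {
      nCard <- .cardinalityValue(ctx, val)
      if (qualified) {
        qKey <- if (propKind == "object") "owl:onClass" else "owl:onDataRange"
        qRow <- predOf(qKey)
        if (length(qRow) != 1L) {
          stopMappingError(sprintf(
            "qualified restriction at %s needs exactly one %s",
            .nodeLabel(e, id), qKey))
        }
        used <- c(used, qRow)
        filler <- if (propKind == "object") .classExpr(ctx, ctx$o[qRow])
                  else .datatypeRef(ctx, ctx$o[qRow])
      }
    }
    expr <- list(type = "restriction", prop = prop, propKind = propKind,
                 kind = kind, filler = filler, n = nCard,
                 qualified = qualified)
  } else {
    boolKeys <- c(intersection = "owl:intersectionOf",
                  union = "owl:unionOf",
                  complement = "owl:complementOf",
                  oneOf = "owl:oneOf")
    hits <- lapply(boolKeys, predOf)
    nHit <- vapply(hits, length, integer(1))
    if (sum(nHit) != 1L) {
      stopMappingError(sprintf(
        "blank node %s does not anchor a well-formed class expression",
        .nodeLabel(e, id)))
    }
    classTypeRow <- typeRows[ctx$o[typeRows] == vocabId("owl:Class")]
    used <- c(used, classTypeRow)
    which1 <- which(nHit == 1L)
    row1 <- hits[[which1]]
    used <- c(used, row1)
    ctor <- names(boolKeys)[which1]
    val <- ctx$o[row1]
    if (ctor == "complement") {
      expr <- list(type = "complement", op = .classExpr(ctx, val))
    } else {
      .consume(ctx, used)  # consume before list walk so cells can't alias
      used <- integer(0)
      members <- .parseListCtx(ctx, val)
      if (ctor == "oneOf") {
        bad <- members[vapply(members, function(m) .isLiteral(ctx, m),
                              logical(1))]
        if (length(bad)) {
          stopMappingError(sprintf(
            "owl:oneOf at %s: member %s is not an individual",
            .nodeLabel(e, id), .nodeLabel(e, bad[1])))
        }
        expr <- list(type = "oneOf", ids = members)
      } else {
        ops <- lapply(members, function(m) .classExpr(ctx, m))
        expr <- list(type = ctor, ops = ops)
      }
    }
  }

  .consume(ctx, used)
  ## strictness: no other triples may hang off an expression node
  left <- .rw(ctx, s = id)
  left <- left[!ctx$consumed[left]]
  if (length(left)) {
    stopMappingError(sprintf(
      "unconsumed extra triples on expression node %s (first predicate: %s)",
      .nodeLabel(e, id), .nodeLabel(e, ctx$p[left[1]])))
  }
  rm(list = key, envir = ctx$inprog)
  assign(key, expr, envir = ctx$memo)
  expr
}

#' Parse a class expression rooted at a node
#'
#' A named IRI declared as a class maps to itself; a blank node carrying
#' `owl:intersectionOf` / `owl:unionOf` / `owl:complementOf` / `owl:oneOf`
#' or typed `owl:Restriction` (with `owl:onProperty` and exactly one filler
#' key) maps to the corresponding structure, recursing through fillers and
#' list members. Undeclared classes, malformed restrictions, bad
#' cardinality literals, cyclic structures and extra triples on a blank
#' expression node each raise a distinct mapping error naming the node.
#'
#' @param store a [TripleStore].
#' @param root NodeId of the expression root.
#' @param decls declarations from [collectDeclarations()]; collected
#'   automatically when omitted.
#' @param doc optional DocId restricting the triples considered.
#' @return a nested list describing the expression (`type` = `"named"`,
#'   `"intersection"`, `"union"`, `"complement"`, `"oneOf"` or
#'   `"restriction"`).
#' @export
parseClassExpression <- function(store, root, decls = NULL, doc = NULL) {
  ctx <- .newMapCtx(store, doc)
  ctx$decls <- if (is.null(decls)) collectDeclarations(store, doc) else decls
  .classExpr(ctx, as.integer(root))
}

## ---- axiom assembly -------------------------------------------------------

.axiom <- function(kind, ..., annotations = list()) {
  structure(list(kind = kind, ..., annotations = annotations),
            class = "OwlAxiom")
}

#' @export
print.OwlAxiom <- function(x, ...) {
  cat(sprintf("<OwlAxiom %s>\n", x$kind))
  invisible(x)
}

## reified owl:Axiom annotation blocks; consumed up front, attached when the
## annotated triple produces its axiom
.collectAxiomAnnotations <- function(ctx) {
  e <- ctx$e
  typeId <- vocabId("rdf:type")
  axId <- vocabId("owl:Axiom")
  blocks <- .rw(ctx, p = typeId, o = axId)
  for (b in blocks) {
    node <- ctx$s[b]
    if (!.isBlank(ctx, node)) {
      stopMappingError(sprintf("owl:Axiom subject %s must be a blank node",
                               .nodeLabel(e, node)))
    }
    here <- .rw(ctx, s = node)
    pick1 <- function(qn) {
      r <- here[ctx$p[here] == vocabId(qn)]
      if (length(r) != 1L) {
        stopMappingError(sprintf(
          "owl:Axiom block %s needs exactly one %s", .nodeLabel(e, node), qn))
      }
      r
    }
    rs <- pick1("owl:annotatedSource")
    rp <- pick1("owl:annotatedProperty")
    rt <- pick1("owl:annotatedTarget")
    annRows <- setdiff(here, c(b, rs, rp, rt))
    anns <- lapply(annRows, function(r) {
      pd <- ctx$p[r]
      if (!.isAnnotationPred(ctx, pd)) {
        stopMappingError(sprintf(
          "owl:Axiom block %s: %s is not an annotation property",
          .nodeLabel(e, node), .nodeLabel(e, pd)))
      }
      list(prop = pd, value = ctx$o[r])
    })
    key <- paste(ctx$o[rs], ctx$o[rp], ctx$o[rt], sep = ",")
    prev <- get0(key, envir = ctx$axAnn, inherits = FALSE)
    assign(key, c(prev, anns), envir = ctx$axAnn)
    .consume(ctx, c(b, rs, rp, rt, annRows))
  }
  invisible(NULL)
}

.isAnnotationPred <- function(ctx, id) {
  .hasKind(ctx$decls, id, "AnnotationProperty")
}

.annFor <- function(ctx, s, p, o) {
  anns <- get0(paste(s, p, o, sep = ","), envir = ctx$axAnn, inherits = FALSE)
  if (is.null(anns)) list() else anns
}

#' Translate triples into OWL 2 axioms
#'
#' Runs the strict two-pass translation over the whole store or one
#' document. Supported axiom forms: declarations, `SubClassOf`,
#' `EquivalentClasses`, `DisjointClasses`, sub-property/domain/range axioms
#' for object, data and annotation properties, the functional /
#' inverse-functional / transitive / symmetric property characteristics,
#' `ClassAssertion`, object/data property assertions, annotation
#' assertions (including reified `owl:Axiom` annotation blocks), and the
#' ontology header with its imports. Constructs outside this set are
#' detected and reported as "unsupported construct" errors rather than
#' silently mis-mapped.
#'
#' @param store a [TripleStore].
#' @param doc optional DocId; when given only that document's triples are
#'   translated.
#' @return a list of axiom objects; serialize with [serializeFunctional()]
#'   or render with [axiomStrings()].
#' @export
mapAxioms <- function(store, doc = NULL) {
  ctx <- .newMapCtx(store, doc)
  e <- ctx$e
  .checkSpelling(ctx)
  ctx$decls <- collectDeclarations(store, doc)

  axioms <- list()
  add <- function(ax) axioms[[length(axioms) + 1L]] <<- ax

  typeId <- vocabId("rdf:type")
  ontoTypeId <- vocabId("owl:Ontology")

  ## ontology header(s)
  ontoAxiomAt <- new.env(parent = emptyenv())  # onto NodeId -> axiom index
  hdr <- .rw(ctx, p = typeId, o = ontoTypeId)
  for (h in hdr) {
    onto <- ctx$s[h]
    if (!.isIriNode(ctx, onto)) {
      stopMappingError("owl:Ontology header subject must be an IRI")
    }
    .consume(ctx, h)
    verRows <- .rw(ctx, s = onto, p = vocabId("owl:versionIRI"))
    ver <- NA_integer_
    if (length(verRows) > 1L) {
      stopMappingError(sprintf("ontology %s has multiple owl:versionIRI",
                               .nodeLabel(e, onto)))
    }
    if (length(verRows) == 1L) {
      ver <- ctx$o[verRows]
      .consume(ctx, verRows)
    }
    impRows <- .rw(ctx, s = onto, p = vocabId("owl:imports"))
    for (r in impRows) {
      if (!.isIriNode(ctx, ctx$o[r])) {
        stopMappingError("owl:imports target must be an IRI")
      }
      add(.axiom("Import", iri = ctx$o[r]))
      .consume(ctx, r)
    }
    add(.axiom("Ontology", iri = onto, version = ver))
    assign(as.character(onto), length(axioms), envir = ontoAxiomAt)
  }

  .collectAxiomAnnotations(ctx)

  ## declarations (consume the declaration triples, emit Declaration axioms)
  declKinds <- .DECL_KINDS()
  declTypeIds <- as.integer(names(declKinds))
  declRows <- which(ctx$p == typeId & ctx$o %in% declTypeIds &
                      !ctx$consumed)
  declRows <- declRows[vapply(declRows, function(r)
    .isIriNode(ctx, ctx$s[r]), logical(1))]
  for (r in declRows) {
    kind <- unname(declKinds[as.character(ctx$o[r])])
    add(.axiom("Declaration", entityKind = kind, id = ctx$s[r],
               annotations = .annFor(ctx, ctx$s[r], typeId, ctx$o[r])))
    .consume(ctx, r)
  }

  structIds <- .qnIds(.STRUCTURE_PRED_QN)
  unsupPredIds <- .qnIds(.UNSUPPORTED_PRED_QN)
  unsupTypeIds <- .qnIds(.UNSUPPORTED_TYPE_QN)
  charIds <- .qnIds(.CHARACTERISTIC_QN)
  names(charIds) <- c("Functional", "InverseFunctional", "Transitive",
                      "Symmetric")
  exprTypeIds <- c(vocabId("owl:Class"), vocabId("owl:Restriction"),
                   vocabId("owl:Axiom"))

  subClassId <- vocabId("rdfs:subClassOf")
  eqClassId <- vocabId("owl:equivalentClass")
  disjId <- vocabId("owl:disjointWith")
  subPropId <- vocabId("rdfs:subPropertyOf")
  domainId <- vocabId("rdfs:domain")
  rangeId <- vocabId("rdfs:range")

  ## assertions whose subject is a blank node are deferred: if the blank
  ## turns out to anchor a class expression, the assertion triple is an
  ## illegal extra triple on that expression node, not an axiom
  deferred <- integer(0)

  for (i in seq_along(ctx$rows)) {
    if (ctx$consumed[i]) next
    s <- ctx$s[i]; p <- ctx$p[i]; o <- ctx$o[i]
    ann <- function() .annFor(ctx, s, p, o)

    if (.isBlank(ctx, s) && .isIriNode(ctx, p) &&
        (.isAnnotationPred(ctx, p) ||
           .hasKind(ctx$decls, p, "ObjectProperty") ||
           .hasKind(ctx$decls, p, "DataProperty"))) {
      deferred <- c(deferred, i)
      next
    }

    ## structural triples on blank nodes are consumed by the expression
    ## parser when the anchoring axiom is reached; skip them here
    if (.isBlank(ctx, s) &&
        (p %in% structIds || (p == typeId && o %in% exprTypeIds))) {
      next
    }

    if (!.isIriNode(ctx, p)) {
      stopMappingError(sprintf(
        "generalized triple with non-IRI predicate %s cannot be mapped",
        .nodeLabel(e, p)))
    }

    if (p %in% unsupPredIds) {
      stopMappingError(sprintf("unsupported construct: predicate %s",
                               .nodeLabel(e, p)),
                       class = "owlstore_unsupported_construct_error")
    }

    if (p == typeId) {
      if (o %in% unsupTypeIds) {
        stopMappingError(sprintf("unsupported construct: rdf:type %s",
                                 .nodeLabel(e, o)),
                         class = "owlstore_unsupported_construct_error")
      }
      if (o %in% charIds) {
        kind <- names(charIds)[match(o, charIds)]
        isOP <- .hasKind(ctx$decls, s, "ObjectProperty")
        isDP <- .hasKind(ctx$decls, s, "DataProperty")
        if (kind == "Functional" && isDP) {
          add(.axiom("FunctionalDataProperty", prop = s,
                     annotations = ann()))
        } else if (isOP) {
          add(.axiom(paste0(kind, "ObjectProperty"), prop = s,
                     annotations = ann()))
        } else {
          stopMappingError(sprintf(
            "property characteristic on %s, which is not a declared property",
            .nodeLabel(e, s)))
        }
        .consume(ctx, i)
        next
      }
      ## class assertion (object may be a named class or a blank expression)
      .consume(ctx, i)
      ce <- .classExpr(ctx, o)
      add(.axiom("ClassAssertion", ce = ce, ind = s, annotations = ann()))
      next
    }

    if (p == subClassId || p == eqClassId || p == disjId) {
      .consume(ctx, i)
      lhs <- .classExpr(ctx, s)
      rhs <- .classExpr(ctx, o)
      kind <- if (p == subClassId) "SubClassOf"
              else if (p == eqClassId) "EquivalentClasses"
              else "DisjointClasses"
      add(.axiom(kind, lhs = lhs, rhs = rhs, annotations = ann()))
      next
    }

    if (p == subPropId || p == domainId || p == rangeId) {
      isOP <- .hasKind(ctx$decls, s, "ObjectProperty")
      isDP <- .hasKind(ctx$decls, s, "DataProperty")
      isAP <- .hasKind(ctx$decls, s, "AnnotationProperty")
      if (!isOP && !isDP && !isAP) {
        stopMappingError(sprintf(
          "%s with subject %s, which is not a declared property",
          .nodeLabel(e, p), .nodeLabel(e, s)))
      }
      .consume(ctx, i)
      if (p == subPropId) {
        kind <- if (isOP) "SubObjectPropertyOf"
                else if (isDP) "SubDataPropertyOf"
                else "SubAnnotationPropertyOf"
        add(.axiom(kind, sub = s, sup = o, annotations = ann()))
      } else if (p == domainId) {
        if (isOP) {
          add(.axiom("ObjectPropertyDomain", prop = s,
                     ce = .classExpr(ctx, o), annotations = ann()))
        } else if (isDP) {
          add(.axiom("DataPropertyDomain", prop = s,
                     ce = .classExpr(ctx, o), annotations = ann()))
        } else {
          add(.axiom("AnnotationPropertyDomain", prop = s, iri = o,
                     annotations = ann()))
        }
      } else {
        if (isOP) {
          add(.axiom("ObjectPropertyRange", prop = s,
                     ce = .classExpr(ctx, o), annotations = ann()))
        } else if (isDP) {
          add(.axiom("DataPropertyRange", prop = s,
                     dt = .datatypeRef(ctx, o), annotations = ann()))
        } else {
          add(.axiom("AnnotationPropertyRange", prop = s, iri = o,
                     annotations = ann()))
        }
      }
      next
    }

    if (.hasKind(ctx$decls, p, "ObjectProperty")) {
      if (.isLiteral(ctx, o)) {
        stopMappingError(sprintf(
          "object property %s used with literal object %s",
          .nodeLabel(e, p), .nodeLabel(e, o)))
      }
      add(.axiom("ObjectPropertyAssertion", prop = p, sub = s, obj = o,
                 annotations = ann()))
      .consume(ctx, i)
      next
    }
    if (.hasKind(ctx$decls, p, "DataProperty")) {
      if (!.isLiteral(ctx, o)) {
        stopMappingError(sprintf(
          "data property %s used with non-literal object %s",
          .nodeLabel(e, p), .nodeLabel(e, o)))
      }
      add(.axiom("DataPropertyAssertion", prop = p, sub = s, obj = o,
                 annotations = ann()))
      .consume(ctx, i)
      next
    }
    if (.isAnnotationPred(ctx, p)) {
      .consume(ctx, i)
      at <- get0(as.character(s), envir = ontoAxiomAt, inherits = FALSE)
      if (!is.null(at)) {
        ## annotations on the ontology header become ontology annotations
        axioms[[at]]$annotations <-
          c(axioms[[at]]$annotations, list(list(prop = p, value = o)))
      } else {
        add(.axiom("AnnotationAssertion", prop = p, sub = s, obj = o,
                   annotations = ann()))
      }
      next
    }

    nsIri <- e$ns_pref[e$node_i1[p]]
    if (!.isStdNamespace(nsIri)) {
      stopMappingError(sprintf(
        "undeclared predicate %s: not built-in vocabulary and not declared as a property",
        .nodeLabel(e, p)),
        class = "owlstore_undeclared_predicate_error")
    }
    stopMappingError(sprintf("triple with predicate %s cannot be mapped here",
                             .nodeLabel(e, p)))
  }

  for (i in deferred) {
    if (ctx$consumed[i]) next
    s <- ctx$s[i]; p <- ctx$p[i]; o <- ctx$o[i]
    if (!is.null(get0(as.character(s), envir = ctx$memo, inherits = FALSE))) {
      stopMappingError(sprintf(
        "unconsumed extra triples on expression node %s (first predicate: %s)",
        .nodeLabel(e, s), .nodeLabel(e, p)))
    }
    .consume(ctx, i)
    if (.hasKind(ctx$decls, p, "ObjectProperty")) {
      add(.axiom("ObjectPropertyAssertion", prop = p, sub = s, obj = o,
                 annotations = .annFor(ctx, s, p, o)))
    } else if (.hasKind(ctx$decls, p, "DataProperty")) {
      add(.axiom("DataPropertyAssertion", prop = p, sub = s, obj = o,
                 annotations = .annFor(ctx, s, p, o)))
    } else {
      add(.axiom("AnnotationAssertion", prop = p, sub = s, obj = o,
                 annotations = .annFor(ctx, s, p, o)))
    }
  }

  ## completeness: every triple in scope must have been consumed
  left <- which(!ctx$consumed)
  if (length(left)) {
    r <- left[1]
    stopMappingError(sprintf(
      "%d triples not consumed by the translation; first: %s %s %s",
      length(left), .nodeLabel(e, ctx$s[r]), .nodeLabel(e, ctx$p[r]),
      .nodeLabel(e, ctx$o[r])))
  }
  axioms
}
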
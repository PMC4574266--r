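## Rendering axioms to OWL 2 functional-style syntax.
##
## Rendering is deterministic: unordered operand sets (EquivalentClasses,
## DisjointClasses, annotation lists) are sorted by their rendered string;
## RDF-list-backed operands (intersections, unions, enumerations) keep
## their source order. axiomStrings() renders with full IRIs — a canonical,
## prefix-independent form used for comparisons — while
## serializeFunctional() produces a complete document with prefix
## declarations for all used namespaces.

.escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

## rendering context: e + optional prefix map (NsId -> prefix name)
.newRenderCtx <- function(store, prefixes = NULL) {
  list(e = store@ptr, prefixes = prefixes)
}

.renderIri <- function(rc, id) {
  e <- rc$e
  ns <- e$node_i1[id]
  frag <- e$node_c1[id]
  if (!is.null(rc$prefixes)) {
    pfx <- rc$prefixes[as.character(ns)]
    if (!is.na(pfx) && nzchar(frag) &&
        grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", frag)) {
      return(paste0(pfx, ":", frag))
    }
  }
  paste0("<", e$ns_pref[ns], frag, ">")
}

.renderLiteral <- function(rc, id) {
  e <- rc$e
  dt <- e$node_i1[id]
  dtIri <- paste0(e$ns_pref[e$node_i1[dt]], e$node_c1[dt])
  lex <- paste0("\"", .escapeLiteral(e$node_c1[id]), "\"")
  lang <- e$node_c2[id]
  if (dtIri %in% .PLAIN_TYPES) {
    if (nzchar(lang)) paste0(lex, "@", lang) else lex
  } else {
    paste0(lex, "^^", .renderIri(rc, dt))
  }
}

.renderNode <- function(rc, id) {
  e <- rc$e
  kind <- e$node_kind[id]
  if (kind == .KIND_IRI) {
    .renderIri(rc, id)
  } else if (kind == .KIND_LIT) {
    .renderLiteral(rc, id)
  } else {
    paste0("_:d", e$node_i1[id], "o", e$node_i2[id])
  }
}

.renderCE <- function(rc, ce) {
  switch(ce$type,
    named = .renderIri(rc, ce$id),
    intersection = sprintf("ObjectIntersectionOf(%s)",
      paste(vapply(ce$ops, function(x) .renderCE(rc, x), character(1)),
            collapse = " ")),
    union = sprintf("ObjectUnionOf(%s)",
      paste(vapply(ce$ops, function(x) .renderCE(rc, x), character(1)),
            collapse = " ")),
    complement = sprintf("ObjectComplementOf(%s)", .renderCE(rc, ce$op)),
    oneOf = sprintf("ObjectOneOf(%s)",
      paste(vapply(ce$ids, function(i) .renderNode(rc, i), character(1)),
            collapse = " ")),
    restriction = .renderRestriction(rc, ce),
    stop("unknown class expression type: ", ce$type)
  )
}

.renderRestriction <- function(rc, ce) {
  obj <- ce$propKind == "object"
  p <- .renderIri(rc, ce$prop)
  fillerStr <- function() {
    if (obj) .renderCE(rc, ce$filler) else .renderIri(rc, ce$filler)
  }
  pre <- if (obj) "Object" else "Data"
  switch(ce$kind,
    some = sprintf("%sSomeValuesFrom(%s %s)", pre, p, fillerStr()),
    only = sprintf("%sAllValuesFrom(%s %s)", pre, p, fillerStr()),
    value = sprintf("%sHasValue(%s %s)", pre, p, .renderNode(rc, ce$filler)),
    min = ,
    max = ,
    exactly = {
      word <- c(min = "Min", max = "Max", exactly = "Exact")[ce$kind]
      if (is.null(ce$filler)) {
        sprintf("%s%sCardinality(%d %s)", pre, word, ce$n, p)
      } else {
        sprintf("%s%sCardinality(%d %s %s)", pre, word, ce$n, p, fillerStr())
      }
    },
    stop("unknown restriction kind: ", ce$kind)
  )
}

.renderAnnotations <- function(rc, anns) {
  if (!length(anns)) return("")
  strs <- vapply(anns, function(a) {
    sprintf("Annotation(%s %s)", .renderIri(rc, a$prop),
            .renderNode(rc, a$value))
  }, character(1))
  paste0(paste(sort(strs, method = "radix"), collapse = " "), " ")
}

.renderAxiom <- function(rc, ax) {
  an <- .renderAnnotations(rc, ax$annotations)
  iri <- function(id) .renderIri(rc, id)
  nd <- function(id) .renderNode(rc, id)
  switch(ax$kind,
    Declaration = sprintf("Declaration(%s%s(%s))", an, ax$entityKind,
                          iri(ax$id)),
    SubClassOf = sprintf("SubClassOf(%s%s %s)", an,
                         .renderCE(rc, ax$lhs), .renderCE(rc, ax$rhs)),
    EquivalentClasses = ,
    DisjointClasses = {
      ops <- sort(c(.renderCE(rc, ax$lhs), .renderCE(rc, ax$rhs)),
                  method = "radix")
      sprintf("%s(%s%s)", ax$kind, an, paste(ops, collapse = " "))
    },
    SubObjectPropertyOf = ,
    SubDataPropertyOf = ,
    SubAnnotationPropertyOf = sprintf("%s(%s%s %s)", ax$kind, an,
                                      iri(ax$sub), iri(ax$sup)),
    ObjectPropertyDomain = ,
    ObjectPropertyRange = ,
    DataPropertyDomain = sprintf("%s(%s%s %s)", ax$kind, an, iri(ax$prop),
                                 .renderCE(rc, ax$ce)),
    DataPropertyRange = sprintf("DataPropertyRange(%s%s %s)", an,
                                iri(ax$prop), iri(ax$dt)),
    AnnotationPropertyDomain = ,
    AnnotationPropertyRange = sprintf("%s(%s%s %s)", ax$kind, an,
                                      iri(ax$prop), iri(ax$iri)),
    FunctionalObjectProperty = ,
    FunctionalDataProperty = ,
    InverseFunctionalObjectProperty = ,
    TransitiveObjectProperty = ,
    SymmetricObjectProperty = sprintf("%s(%s%s)", ax$kind, an, iri(ax$prop)),
    ClassAssertion = sprintf("ClassAssertion(%s%s %s)", an,
                             .renderCE(rc, ax$ce), nd(ax$ind)),
    ObjectPropertyAssertion = sprintf("ObjectPropertyAssertion(%s%s %s %s)",
                                      an, iri(ax$prop), nd(ax$sub),
                                      nd(ax$obj)),
    DataPropertyAssertion = sprintf("DataPropertyAssertion(%s%s %s %s)",
                                    an, iri(ax$prop), nd(ax$sub),
                                    nd(ax$obj)),
    AnnotationAssertion = sprintf("AnnotationAssertion(%s%s %s %s)", an,
                                  iri(ax$prop), nd(ax$sub), nd(ax$obj)),
    Import = sprintf("Import(%s)", iri(ax$iri)),
    Ontology = {
      if (is.na(ax$version)) {
        sprintf("Ontology(%s%s)", an, iri(ax$iri))
      } else {
        sprintf("Ontology(%s%s %s)", an, iri(ax$iri), iri(ax$version))
      }
    },
    stop("unknown axiom kind: ", ax$kind)
  )
}

#' Canonical full-IRI strings for a list of axioms
#'
#' Each axiom is rendered to exactly one functional-style-syntax string
#' with full IRIs (no prefixes) and deterministic operand order — a
#' convenient form for set comparisons and tests.
#'
#' @param axioms list of axioms from [mapAxioms()].
#' @param store the [TripleStore] the axioms refer to.
#' @return character vector, one string per axiom (same order as input).
#' @export
axiomStrings <- function(axioms, store) {
  rc <- .newRenderCtx(store)
  vapply(axioms, function(ax) .renderAxiom(rc, ax), character(1))
}

## ---- document serialization -----------------------------------------------

## every NodeId mentioned by an axiom (for prefix collection)
.axiomNodeIds <- function(ax) {
  ids <- integer(0)
  grab <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x) && !is.null(x$type)) {
      switch(x$type,
        named = ids <<- c(ids, x$id),
        intersection = ,
        union = lapply(x$ops, grab),
        complement = grab(x$op),
        oneOf = ids <<- c(ids, x$ids),
        restriction = {
          ids <<- c(ids, x$prop)
          if (!is.null(x$filler)) {
            if (is.list(x$filler)) grab(x$filler) else ids <<- c(ids, x$filler)
          }
        })
      return(invisible(NULL))
    }
    invisible(NULL)
  }
  for (f in c("id", "iri", "version", "prop", "sub", "sup", "obj", "ind",
              "dt")) {
    v <- ax[[f]]
    if (!is.null(v) && !is.na(v)) ids <- c(ids, v)
  }
  for (f in c("lhs", "rhs", "ce")) grab(ax[[f]])
  for (a in ax$annotations) ids <- c(ids, a$prop, a$value)
  ids
}

.STD_PREFIX_OF <- c(rdf = .NS_RDF, rdfs = .NS_RDFS, owl = .NS_OWL,
                    xsd = .NS_XSD)

## deterministic prefix names for a set of namespace prefix-IRIs
.assignPrefixes <- function(e, nsIds) {
  iris <- e$ns_pref[nsIds]
  ord <- order(iris, method = "radix")
  nsIds <- nsIds[ord]
  iris <- iris[ord]
  out <- character(length(nsIds))
  taken <- character(0)
  for (i in seq_along(nsIds)) {
    std <- names(.STD_PREFIX_OF)[match(iris[i], .STD_PREFIX_OF)]
    if (!is.na(std)) {
      cand <- std
    } else {
      stem <- sub("[#/]+$", "", iris[i])
      stem <- sub("^.*[/#]", "", stem)
      stem <- gsub("[^A-Za-z0-9_-]", "", stem)
      cand <- if (grepl("^[A-Za-z]", stem)) stem else "ns"
    }
    base <- cand
    k <- 1L
    while (cand %in% taken) {
      k <- k + 1L
      cand <- paste0(base, k)
    }
    taken <- c(taken, cand)
    out[i] <- cand
  }
  stats::setNames(out, as.character(nsIds))
}

.AXIOM_KIND_ORDER <- c(
  "SubClassOf", "EquivalentClasses", "DisjointClasses",
  "SubObjectPropertyOf", "SubDataPropertyOf", "SubAnnotationPropertyOf",
  "ObjectPropertyDomain", "ObjectPropertyRange", "DataPropertyDomain",
  "DataPropertyRange", "AnnotationPropertyDomain", "AnnotationPropertyRange",
  "FunctionalObjectProperty", "FunctionalDataProperty",
  "InverseFunctionalObjectProperty", "TransitiveObjectProperty",
  "SymmetricObjectProperty", "ClassAssertion", "ObjectPropertyAssertion",
  "DataPropertyAssertion", "AnnotationAssertion"
)

#' Serialize axioms to an OWL 2 functional-style syntax document
#'
#' Produces a complete document: `Prefix` declarations for every namespace
#' used, then one `Ontology( ... )` block containing imports, ontology
#' annotations, declarations (first, sorted), and the remaining axioms
#' sorted by kind and rendered form. The output is deterministic for a
#' given axiom set.
#'
#' @param axioms list of axioms from [mapAxioms()].
#' @param store the [TripleStore] the axioms refer to.
#' @param file optional path; when given the text is also written there.
#' @return the document as a single character string (invisibly when
#'   `file` is given).
#' @export
serializeFunctional <- function(axioms, store, file = NULL) {
  e <- store@ptr
  kinds <- vapply(axioms, `[[`, character(1), "kind")

  allIds <- unique(unlist(lapply(axioms, .axiomNodeIds)))
  allIds <- allIds[!is.na(allIds)]
  iriIds <- allIds[e$node_kind[allIds] == .KIND_IRI]
  litIds <- allIds[e$node_kind[allIds] == .KIND_LIT]
  nsIds <- unique(c(e$node_i1[iriIds], e$node_i1[e$node_i1[litIds]]))
  prefixes <- .assignPrefixes(e, nsIds)
  rc <- list(e = e, prefixes = prefixes)

  header <- vapply(names(prefixes), function(ns) {
    sprintf("Prefix(%s:=<%s>)", prefixes[[ns]], e$ns_pref[as.integer(ns)])
  }, character(1))
  header <- sort(header, method = "radix")

  ontoAx <- axioms[kinds == "Ontology"]
  imports <- sort(vapply(axioms[kinds == "Import"], function(ax)
    sprintf("Import(%s)", .renderIri(rc, ax$iri)), character(1)),
    method = "radix")

  ontoLine <- if (length(ontoAx)) {
    first <- ontoAx[[1]]
    if (is.na(first$version)) {
      .renderIri(rc, first$iri)
    } else {
      paste(.renderIri(rc, first$iri), .renderIri(rc, first$version))
    }
  } else {
    ""
  }
  ontoAnns <- if (length(ontoAx)) {
    sort(vapply(ontoAx[[1]]$annotations, function(a)
      sprintf("Annotation(%s %s)", .renderIri(rc, a$prop),
              .renderNode(rc, a$value)), character(1)), method = "radix")
  } else {
    character(0)
  }

  decls <- axioms[kinds == "Declaration"]
  declLines <- sort(vapply(decls, function(ax) .renderAxiom(rc, ax),
                           character(1)), method = "radix")

  rest <- axioms[!(kinds %in% c("Ontology", "Import", "Declaration"))]
  restKinds <- vapply(rest, `[[`, character(1), "kind")
  restLines <- vapply(rest, function(ax) .renderAxiom(rc, ax), character(1))
  kindRank <- match(restKinds, .AXIOM_KIND_ORDER, nomatch = 99L)
  restLines <- restLines[order(kindRank, restLines, method = "radix")]

  body <- c(imports, ontoAnns, declLines, restLines)
  txt <- paste0(
    paste(header, collapse = "\n"),
    if (length(header)) "\n\n" else "",
    "Ontology(", ontoLine, "\n",
    if (length(body)) paste0(paste(body, collapse = "\n"), "\n") else "",
    ")\n"
  )
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}
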
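#' @import methods
NULL

#' An in-memory, index-backed RDF triple store
#'
#' `TripleStore` is the central container of the package. It interns
#' namespace prefix IRIs, RDF terms (IRI, literal and blank nodes) and
#' ontology document descriptors to light-weight integer IDs, and stores
#' generalized RDF quads (subject, predicate, object, source document) in a
#' configurable set of bin-and-sort indices for fast pattern search.
#'
#' The object has reference semantics: all data live in an environment, so
#' mutating operations such as [addTriple()] modify the store in place.
#' Read-only operations are safe to interleave; a mutating operation
#' requires exclusive access (no locking is provided).
#'
#' A fresh store is not empty: the standard RDF, RDFS, OWL 2 and XSD
#' vocabularies are pre-interned in a fixed order, so their IDs are
#' constants shared by every store (see [vocabId()]).
#'
#' @slot ptr environment holding the interning tables, triples and indices.
#' @seealso [TripleStore()], [findTriple()], [loadOntologyFile()],
#'   [mapAxioms()]
#' @export
setClass("TripleStore", representation(ptr = "environment"))

setValidity("TripleStore", function(object) {
  e <- object@ptr
  need <- c("ns_pref", "node_kind", "ts", "tp", "to", "td", "nt", "idx")
  miss <- need[!vapply(need, exists, logical(1), envir = e, inherits = FALSE)]
  if (length(miss)) {
    return(sprintf("store environment is missing fields: %s",
                   paste(miss, collapse = ", ")))
  }
  if (length(e$idx) < 1L) return("store must have at least one triple index")
  TRUE
})

#' A catalog of ontology documents on the filesystem
#'
#' Maps ontology IRIs and version IRIs to file paths, so that `owl:imports`
#' statements can be resolved locally (documents are never fetched from the
#' Internet). Build one with [scanOntologyDir()].
#'
#' @slot entries a data.frame with columns `path`, `ontology_iri`,
#'   `version_iri` (`NA` when the document declares none).
#' @seealso [resolveIri()], [loadOntologyFile()]
#' @export
setClass("OntologyCatalog", representation(entries = "data.frame"))

setValidity("OntologyCatalog", function(object) {
  en <- object@entries
  if (!all(c("path", "ontology_iri", "version_iri") %in% names(en))) {
    return("entries must have columns path, ontology_iri, version_iri")
  }
  if (anyDuplicated(en$path)) return("catalog paths must be unique")
  TRUE
})

## ---- RDF term record classes (returned by getNode() etc.) ----------------

#' @export
setClass("Node", representation("VIRTUAL", id = "integer"))

#' An IRI node: a namespace prefix plus an optional fragment
#' @export
setClass("NodeIri", contains = "Node",
         representation(ns = "integer", nsIri = "character",
                        fragment = "character", iri = "character"))

#' A typed literal node
#' @export
setClass("NodeLiteral", contains = "Node",
         representation(datatype = "integer", datatypeIri = "character",
                        lexical = "character", language = "character",
                        value = "ANY"))

#' A blank node, scoped to its source document
#' @export
setClass("NodeBlank", contains = "Node",
         representation(doc = "integer", ordinal = "integer"))

#' A namespace prefix IRI record
#' @export
setClass("NsIri", representation(id = "integer", iri = "character"))

#' An ontology document descriptor
#' @export
setClass("DocMeta",
         representation(id = "integer", path = "character",
                        ontologyIri = "character", versionIri = "character"))

setMethod("show", "NodeIri", function(object) {
  cat(sprintf("NodeIri #%d <%s>\n", object@id, object@iri))
})
setMethod("show", "NodeLiteral", function(object) {
  lang <- if (nzchar(object@language)) paste0("@", object@language) else ""
  cat(sprintf("NodeLiteral #%d \"%s\"%s ^^<%s>\n",
              object@id, object@lexical, lang, object@datatypeIri))
})
setMethod("show", "NodeBlank", function(object) {
  cat(sprintf("NodeBlank #%d doc=%d ordinal=%d\n",
              object@id, object@doc, object@ordinal))
})
setMethod("show", "NsIri", function(object) {
  cat(sprintf("NsIri #%d <%s>\n", object@id, object@iri))
})
setMethod("show", "DocMeta", function(object) {
  cat(sprintf("DocMeta #%d path=%s ontology=%s version=%s\n",
              object@id, object@path, object@ontologyIri, object@versionIri))
})

## ---- index configuration --------------------------------------------------

.IDX_KEYS <- c("s", "p", "o", "d")

#' Parse a triple-index layout specification
#'
#' An index layout is written `"<bin>:<k1><k2><k3>"`, e.g. `"s:pod"`: bin
#' triples by subject, and sort each bin by predicate, then object, then
#' document. The three sort keys must be exactly the keys other than the bin
#' key. Several layouts are separated by commas.
#'
#' @param spec a layout string such as `"s:pod,o:psd"`.
#' @return a list of layouts, each a list with elements `bin` (one of
#'   `"s","p","o","d"`) and `sort` (character vector of the other three).
#' @examples
#' parseIndexSpec("s:pod,o:psd")
#' @export
parseIndexSpec <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stopConfigError("empty index specification")
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([spod]):([spod]{3})$", p))[[1]]
    if (length(m) != 3L) {
      stopConfigError(sprintf("bad index layout '%s' (expected e.g. 's:pod')", p))
    }
    bin <- m[2]
    srt <- strsplit(m[3], "")[[1]]
    if (bin %in% srt || anyDuplicated(srt) ||
        !setequal(c(bin, srt), .IDX_KEYS)) {
      stopConfigError(sprintf(
        "index layout '%s': sort keys must be the three keys other than the bin key", p))
    }
    list(bin = bin, sort = srt)
  })
}

#' The default index configuration
#'
#' Two indices: bin by subject sorted by predicate, object, document, and
#' bin by object sorted by predicate, subject, document. This pairing was
#' chosen because subject(+predicate) and object(+predicate) lookups
#' dominate axiom generation.
#'
#' @return a list of index layouts (see [parseIndexSpec()]).
#' @export
defaultIndexConfig <- function() parseIndexSpec("s:pod,o:psd")

.indexLabel <- function(layout) {
  paste0(layout$bin, ":", paste(layout$sort, collapse = ""))
}

.checkIndexConfig <- function(config) {
  if (is.character(config)) config <- parseIndexSpec(paste(config, collapse = ","))
  if (!is.list(config) || !length(config)) {
    stopConfigError("index configuration must be a non-empty list of layouts")
  }
  config <- lapply(config, function(l) {
    if (!is.list(l) || !all(c("bin", "sort") %in% names(l))) {
      stopConfigError("each index layout needs fields 'bin' and 'sort'")
    }
    if (l$bin %in% l$sort || !setequal(c(l$bin, l$sort), .IDX_KEYS)) {
      stopConfigError("index bin key must be distinct from its three sort keys")
    }
    l
  })
  labels <- vapply(config, .indexLabel, character(1))
  if (anyDuplicated(labels)) {
    stopConfigError(sprintf("duplicate index layout: %s",
                            labels[duplicated(labels)][1]))
  }
  config
}

#' Create a triple store
#'
#' @param indexes index configuration: a layout string such as
#'   `"s:pod,o:psd"` or a list as returned by [parseIndexSpec()]. Defaults
#'   to [defaultIndexConfig()].
#' @return a [TripleStore] pre-loaded with the standard vocabulary and no
#'   triples.
#' @examples
#' st <- TripleStore()
#' tripleCount(st)
#' lookupIri(st, "http://www.w3.org/2002/07/owl#Class")
#' @export
TripleStore <- function(indexes = defaultIndexConfig()) {
  config <- .checkIndexConfig(indexes)
  e <- new.env(parent = emptyenv())

  e$ns_pref <- character(0)
  e$ns_map <- new.env(parent = emptyenv())

  ## node tables: kind 1=IRI, 2=literal, 3=blank
  e$node_kind <- integer(0)
  e$node_i1 <- integer(0)    # IRI: ns id | literal: datatype id | blank: doc id
  e$node_i2 <- integer(0)    # blank: ordinal
  e$node_c1 <- character(0)  # IRI: fragment | literal: canonical lexical
  e$node_c2 <- character(0)  # literal: language
  e$node_pay <- list()       # literal: typed payload
  e$node_map <- new.env(parent = emptyenv())

  e$doc_path <- character(0)
  e$doc_onto <- integer(0)   # NodeId or NA
  e$doc_ver <- integer(0)    # NodeId or NA
  e$doc_blank_n <- integer(0)
  e$doc_map <- new.env(parent = emptyenv())

  ## triples: preallocated columns + fill counter
  e$ts <- integer(64); e$tp <- integer(64); e$to <- integer(64); e$td <- integer(64)
  e$nt <- 0L
  e$trip_map <- new.env(parent = emptyenv())

  e$idx <- lapply(config, function(l) {
    list(bin = l$bin, sort = l$sort, ord = integer(0), built = 0L)
  })

  e$txn <- NULL

  st <- new("TripleStore", ptr = e)
  .internVocab(e)
  st
}

setMethod("show", "TripleStore", function(object) {
  e <- object@ptr
  labs <- vapply(e$idx, .indexLabel, character(1))
  cat(sprintf(
    "TripleStore: %d triples, %d nodes, %d namespaces, %d documents\n",
    e$nt, length(e$node_kind), length(e$ns_pref), length(e$doc_path)))
  cat(sprintf("  indices: %s\n", paste(labs, collapse = ", ")))
})
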
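## Interning tables and triple insertion.
##
## All mutating operations funnel through the .j* helpers so that an active
## transaction (see load.R) can roll every append back: appends are the only
## kind of mutation the store performs, so a rollback is a truncation of the
## table vectors plus removal of the journalled hash-map keys.

.KIND_IRI <- 1L
.KIND_LIT <- 2L
.KIND_BLANK <- 3L

## record a key added to map `what` while a transaction is active
.jKey <- function(e, what, key) {
  if (!is.null(e$txn)) assign(key, TRUE, envir = e$txn$keys[[what]])
  invisible(NULL)
}

## ---- IRI splitting --------------------------------------------------------

## Split an absolute IRI into (prefix, fragment) at the last '#' if present,
## else the last '/'. The separator stays with the prefix so that
## prefix + fragment reconstructs the input exactly.
.splitIri <- function(iri) {
  h <- regexpr("#[^#]*$", iri)
  if (h > 0L) {
    return(c(substr(iri, 1L, h), substring(iri, h + 1L)))
  }
  s <- regexpr("/[^/]*$", iri)
  if (s > 0L) {
    return(c(substr(iri, 1L, s), substring(iri, s + 1L)))
  }
  c(iri, "")
}

.isAbsoluteIri <- function(iri) {
  nzchar(iri) & grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri)
}

.internNs <- function(e, prefix) {
  id <- get0(prefix, envir = e$ns_map, inherits = FALSE)
  if (!is.null(id)) return(id)
  id <- length(e$ns_pref) + 1L
  e$ns_pref[id] <- prefix
  assign(prefix, id, envir = e$ns_map)
  .jKey(e, "ns", prefix)
  id
}

.appendNode <- function(e, kind, i1 = NA_integer_, i2 = NA_integer_,
                        c1 = NA_character_, c2 = NA_character_, pay = NULL) {
  id <- length(e$node_kind) + 1L
  e$node_kind[id] <- kind
  e$node_i1[id] <- i1
  e$node_i2[id] <- i2
  e$node_c1[id] <- c1
  e$node_c2[id] <- c2
  e$node_pay[id] <- list(pay)  # list(NULL) keeps the slot, extends length
  id
}

.internIri1 <- function(e, iri) {
  key <- paste0("i\x01", iri)
  id <- get0(key, envir = e$node_map, inherits = FALSE)
  if (!is.null(id)) return(id)
  parts <- .splitIri(iri)
  ns <- .internNs(e, parts[1])
  id <- .appendNode(e, .KIND_IRI, i1 = ns, c1 = parts[2])
  assign(key, id, envir = e$node_map)
  .jKey(e, "node", key)
  id
}

.internVocab <- function(e) {
  for (p in unname(.VOCAB_NS)) .internNs(e, p)
  for (i in seq_len(nrow(.vocabTable))) .internIri1(e, .vocabTable$iri[i])
  invisible(NULL)
}

#' Intern an IRI
#'
#' Adds the IRI to the store's node table (splitting it into a namespace
#' prefix, interned as a side effect, and an optional fragment) and returns
#' its NodeId. Interning the same string twice returns the same NodeId.
#'
#' @param store a [TripleStore].
#' @param iri character vector of absolute IRIs.
#' @return integer vector of NodeIds, one per input.
#' @examples
#' st <- TripleStore()
#' internIri(st, "http://example.org/vocab#Dog")
#' @export
internIri <- function(store, iri) {
  e <- store@ptr
  if (!length(iri)) return(integer(0))
  bad <- !.isAbsoluteIri(iri)
  if (any(bad)) {
    stopValueError(sprintf("not an absolute IRI: %s", deparse(iri[bad][1])))
  }
  vapply(iri, function(x) .internIri1(e, x), integer(1), USE.NAMES = FALSE)
}

#' Look up an IRI without interning it
#'
#' @param store a [TripleStore].
#' @param iri character vector of absolute IRIs.
#' @return integer vector of NodeIds, `NA` where the IRI is not in the store.
#' @export
lookupIri <- function(store, iri) {
  e <- store@ptr
  vapply(iri, function(x) {
    id <- get0(paste0("i\x01", x), envir = e$node_map, inherits = FALSE)
    if (is.null(id)) NA_integer_ else id
  }, integer(1), USE.NAMES = FALSE)
}

## ---- literals -------------------------------------------------------------

.XSD_INTEGER_TYPES <- paste0(.NS_XSD, c(
  "integer", "int", "long", "short", "byte", "nonNegativeInteger",
  "positiveInteger", "nonPositiveInteger", "negativeInteger",
  "unsignedLong", "unsignedInt", "unsignedShort", "unsignedByte"
))
.XSD_REAL_TYPES <- paste0(.NS_XSD, c("decimal", "float", "double"))
.PLAIN_TYPES <- c(paste0(.NS_RDF, c("PlainLiteral", "langString")),
                  paste0(.NS_XSD, "string"))

## Parse + canonicalize a lexical form under a datatype IRI.
## Returns list(canon = character, value = payload).
.parseLiteral <- function(lexical, dtIri) {
  if (dtIri == paste0(.NS_XSD, "boolean")) {
    v <- trimws(lexical)
    if (v %in% c("true", "1")) return(list(canon = "true", value = TRUE))
    if (v %in% c("false", "0")) return(list(canon = "false", value = FALSE))
    stopLiteralParseError(lexical, dtIri)
  }
  if (dtIri %in% .XSD_INTEGER_TYPES) {
    v <- trimws(lexical)
    if (!grepl("^[+-]?[0-9]+$", v)) stopLiteralParseError(lexical, dtIri)
    neg <- startsWith(v, "-")
    digits <- sub("^[+-]", "", v)
    digits <- sub("^0+(?=[0-9])", "", digits, perl = TRUE)
    canon <- paste0(if (neg && digits != "0") "-" else "", digits)
    return(list(canon = canon, value = as.numeric(canon)))
  }
  if (dtIri %in% .XSD_REAL_TYPES) {
    v <- suppressWarnings(as.numeric(trimws(lexical)))
    if (is.na(v)) stopLiteralParseError(lexical, dtIri)
    return(list(canon = sprintf("%.17g", v), value = v))
  }
  ## strings, dates, XMLLiteral, unknown datatypes: raw lexical form
  list(canon = lexical, value = lexical)
}

#' Intern a typed literal
#'
#' The lexical form is parsed into a typed payload according to the
#' datatype (boolean, integer and floating-point types get native payloads;
#' everything else is kept as a string). Node identity is defined by
#' (datatype, canonical payload, language), so `"1"^^xsd:boolean` and
#' `"true"^^xsd:boolean` intern to the same NodeId.
#'
#' @param store a [TripleStore].
#' @param lexical the lexical form, a single string.
#' @param datatype datatype as a NodeId, a full IRI, or `NULL` for a plain
#'   literal (`rdf:PlainLiteral`).
#' @param language BCP-47 language tag; must be empty unless the datatype is
#'   plain/string.
#' @return the literal's integer NodeId.
#' @examples
#' st <- TripleStore()
#' internLiteral(st, "1", "http://www.w3.org/2001/XMLSchema#boolean")
#' @export
internLiteral <- function(store, lexical, datatype = NULL, language = "") {
  e <- store@ptr
  if (is.null(datatype)) {
    dt <- vocabId("rdf:PlainLiteral")
  } else if (is.character(datatype)) {
    dt <- .internIri1(e, datatype)
  } else {
    dt <- as.integer(datatype)
  }
  if (dt < 1L || dt > length(e$node_kind) || e$node_kind[dt] != .KIND_IRI) {
    stopValueError("literal datatype must resolve to an IRI node")
  }
  dtIri <- paste0(e$ns_pref[e$node_i1[dt]], e$node_c1[dt])
  if (nzchar(language) && !(dtIri %in% .PLAIN_TYPES)) {
    stopValueError(sprintf(
      "language tag %s not allowed for datatype <%s>", deparse(language), dtIri))
  }
  p <- .parseLiteral(lexical, dtIri)
  key <- paste0("l\x01", dt, "\x01", language, "\x01", p$canon)
  id <- get0(key, envir = e$node_map, inherits = FALSE)
  if (!is.null(id)) return(id)
  id <- .appendNode(e, .KIND_LIT, i1 = dt, c1 = p$canon, c2 = language,
                    pay = p$value)
  assign(key, id, envir = e$node_map)
  .jKey(e, "node", key)
  id
}

## ---- blank nodes ----------------------------------------------------------

#' Create or retrieve a blank node
#'
#' Blank nodes are scoped to their source document: the same label under the
#' same document always yields the same NodeId, while equal labels from
#' different documents are always kept distinct. Ordinals within a document
#' are assigned 0, 1, 2, ... in first-seen order.
#'
#' @param store a [TripleStore].
#' @param doc a registered DocId.
#' @param label the blank node label used in the source document.
#' @return the blank node's integer NodeId.
#' @export
makeBlank <- function(store, doc, label) {
  e <- store@ptr
  doc <- as.integer(doc)
  if (is.na(doc) || doc < 1L || doc > length(e$doc_path)) {
    stopLookupError(sprintf("unknown document id: %s", doc))
  }
  key <- paste0("b\x01", doc, "\x01", label)
  id <- get0(key, envir = e$node_map, inherits = FALSE)
  if (!is.null(id)) return(id)
  ord <- e$doc_blank_n[doc]
  e$doc_blank_n[doc] <- ord + 1L
  id <- .appendNode(e, .KIND_BLANK, i1 = doc, i2 = ord)
  assign(key, id, envir = e$node_map)
  .jKey(e, "node", key)
  id
}

## ---- documents ------------------------------------------------------------

#' Register an ontology document descriptor
#'
#' Normally called by the loader; exposed so that blank nodes and triples
#' can also be created programmatically.
#'
#' @param store a [TripleStore].
#' @param path filesystem path (or any unique string identifying the
#'   document).
#' @param ontologyIri,versionIri NodeIds of the ontology/version IRI nodes,
#'   or `NA` when the document declares none.
#' @return the new integer DocId.
#' @export
registerDocument <- function(store, path, ontologyIri = NA_integer_,
                             versionIri = NA_integer_) {
  e <- store@ptr
  if (!is.null(get0(path, envir = e$doc_map, inherits = FALSE))) {
    stopValueError(sprintf("document path already registered: %s", path))
  }
  id <- length(e$doc_path) + 1L
  e$doc_path[id] <- path
  e$doc_onto[id] <- as.integer(ontologyIri)
  e$doc_ver[id] <- as.integer(versionIri)
  e$doc_blank_n[id] <- 0L
  assign(path, id, envir = e$doc_map)
  .jKey(e, "doc", path)
  id
}

#' Look up a document by path
#' @param store a [TripleStore].
#' @param path the path the document was registered under.
#' @return integer DocId or `NA`.
#' @export
lookupDocument <- function(store, path) {
  id <- get0(path, envir = store@ptr$doc_map, inherits = FALSE)
  if (is.null(id)) NA_integer_ else id
}

## ---- triples --------------------------------------------------------------

.growTriples <- function(e, need) {
  cap <- length(e$ts)
  if (need <= cap) return(invisible(NULL))
  newcap <- max(need, cap * 2L)
  length(e$ts) <- newcap; length(e$tp) <- newcap
  length(e$to) <- newcap; length(e$td) <- newcap
  invisible(NULL)
}

.checkNodeIds <- function(e, ids, what) {
  n <- length(e$node_kind)
  bad <- is.na(ids) | ids < 1L | ids > n
  if (any(bad)) {
    stopLookupError(sprintf("%s id %s does not resolve in this store",
                            what, ids[bad][1]))
  }
}

## Vectorized insertion; duplicates of (s,p,o,doc) — both against the store
## and within the batch — are dropped. Returns number of triples added.
.addTriplesRaw <- function(e, s, p, o, d) {
  n <- length(s)
  if (!n) return(0L)
  .checkNodeIds(e, s, "subject")
  .checkNodeIds(e, p, "predicate")
  .checkNodeIds(e, o, "object")
  nd <- length(e$doc_path)
  badd <- is.na(d) | d < 1L | d > nd
  if (any(badd)) {
    stopLookupError(sprintf("document id %s does not resolve in this store",
                            d[badd][1]))
  }
  keys <- paste(s, p, o, d, sep = "\x01")
  inStore <- vapply(keys, function(k) {
    !is.null(get0(k, envir = e$trip_map, inherits = FALSE))
  }, logical(1), USE.NAMES = FALSE)
  keep <- !inStore & !duplicated(keys)
  if (!any(keep)) return(0L)
  s <- s[keep]; p <- p[keep]; o <- o[keep]; d <- d[keep]; keys <- keys[keep]
  m <- length(s)
  at <- e$nt
  .growTriples(e, at + m)
  e$ts[(at + 1L):(at + m)] <- s
  e$tp[(at + 1L):(at + m)] <- p
  e$to[(at + 1L):(at + m)] <- o
  e$td[(at + 1L):(at + m)] <- d
  e$nt <- at + m
  for (k in keys) {
    assign(k, TRUE, envir = e$trip_map)
    .jKey(e, "trip", k)
  }
  m
}

#' Add triples to the store
#'
#' Triples are generalized: no positional type restriction is enforced, so
#' e.g. a literal subject is representable. Inserting a triple that is
#' already present (same subject, predicate, object *and* document) is a
#' no-op; the same (s, p, o) from different documents is stored separately,
#' because the source document is part of triple identity.
#'
#' @param store a [TripleStore].
#' @param subj,pred,obj integer NodeIds (vectors of equal length are
#'   accepted).
#' @param doc integer DocId(s).
#' @return invisibly, the number of triples actually added.
#' @export
addTriple <- function(store, subj, pred, obj, doc) {
  n <- max(length(subj), length(pred), length(obj), length(doc))
  added <- .addTriplesRaw(store@ptr,
                          rep_len(as.integer(subj), n),
                          rep_len(as.integer(pred), n),
                          rep_len(as.integer(obj), n),
                          rep_len(as.integer(doc), n))
  invisible(added)
}

## ---- accessors ------------------------------------------------------------

#' Store size accessors
#'
#' @param store a [TripleStore].
#' @return an integer count.
#' @export
tripleCount <- function(store) store@ptr$nt

#' @rdname tripleCount
#' @export
nodeCount <- function(store) length(store@ptr$node_kind)

#' @rdname tripleCount
#' @export
namespaceCount <- function(store) length(store@ptr$ns_pref)

#' @rdname tripleCount
#' @export
documentCount <- function(store) length(store@ptr$doc_path)

#' All triples currently stored
#' @param store a [TripleStore].
#' @return a data.frame with integer columns `subj`, `pred`, `obj`, `doc`.
#' @export
triples <- function(store) {
  e <- store@ptr
  n <- e$nt
  data.frame(subj = e$ts[seq_len(n)], pred = e$tp[seq_len(n)],
             obj = e$to[seq_len(n)], doc = e$td[seq_len(n)])
}

#' Retrieve an interned object by its ID
#'
#' The inverse of interning: `getNode()` returns the [Node] record for a
#' NodeId, `getNsIri()` the [NsIri] for an NsId, and `getDocument()` the
#' [DocMeta] for a DocId. `getObject()` dispatches on the `type` argument.
#'
#' @param store a [TripleStore].
#' @param id an integer ID issued by this store.
#' @param type one of `"node"`, `"ns"`, `"doc"`.
#' @return a [NodeIri], [NodeLiteral], [NodeBlank], [NsIri] or [DocMeta].
#' @export
getObject <- function(store, id, type = c("node", "ns", "doc")) {
  switch(match.arg(type),
         node = getNode(store, id),
         ns = getNsIri(store, id),
         doc = getDocument(store, id))
}

#' @rdname getObject
#' @export
getNode <- function(store, id) {
  e <- store@ptr
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > length(e$node_kind)) {
    stopLookupError(sprintf("node id %s was not issued by this store", id))
  }
  kind <- e$node_kind[id]
  if (kind == .KIND_IRI) {
    ns <- e$node_i1[id]
    new("NodeIri", id = id, ns = ns, nsIri = e$ns_pref[ns],
        fragment = e$node_c1[id],
        iri = paste0(e$ns_pref[ns], e$node_c1[id]))
  } else if (kind == .KIND_LIT) {
    dt <- e$node_i1[id]
    new("NodeLiteral", id = id, datatype = dt,
        datatypeIri = paste0(e$ns_pref[e$node_i1[dt]], e$node_c1[dt]),
        lexical = e$node_c1[id], language = e$node_c2[id],
        value = e$node_pay[[id]])
  } else {
    new("NodeBlank", id = id, doc = e$node_i1[id], ordinal = e$node_i2[id])
  }
}

#' @rdname getObject
#' @export
getNsIri <- function(store, id) {
  e <- store@ptr
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > length(e$ns_pref)) {
    stopLookupError(sprintf("namespace id %s was not issued by this store", id))
  }
  new("NsIri", id = id, iri = e$ns_pref[id])
}

#' @rdname getObject
#' @export
getDocument <- function(store, id) {
  e <- store@ptr
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > length(e$doc_path)) {
    stopLookupError(sprintf("document id %s was not issued by this store", id))
  }
  onto <- e$doc_onto[id]
  ver <- e$doc_ver[id]
  new("DocMeta", id = id, path = e$doc_path[id],
      ontologyIri = if (is.na(onto)) NA_character_ else .iriString(e, onto),
      versionIri = if (is.na(ver)) NA_character_ else .iriString(e, ver))
}

.iriString <- function(e, id) paste0(e$ns_pref[e$node_i1[id]], e$node_c1[id])

#' Full IRI string of an IRI node
#' @param store a [TripleStore].
#' @param id integer NodeId(s) of IRI nodes.
#' @return character vector of absolute IRIs.
#' @export
iriOf <- function(store, id) {
  e <- store@ptr
  vapply(as.integer(id), function(i) {
    if (is.na(i) || i < 1L || i > length(e$node_kind) ||
        e$node_kind[i] != .KIND_IRI) {
      stopLookupError(sprintf("node id %s is not an IRI node of this store", i))
    }
    .iriString(e, i)
  }, character(1))
}

## ---- store cloning (index studies) ---------------------------------------

## Same contents (identical IDs), different index configuration.
.cloneStore <- function(store, indexes) {
  config <- .checkIndexConfig(indexes)
  e <- store@ptr
  e2 <- new.env(parent = emptyenv())
  for (f in c("ns_pref", "node_kind", "node_i1", "node_i2", "node_c1",
              "node_c2", "node_pay", "doc_path", "doc_onto", "doc_ver",
              "doc_blank_n", "ts", "tp", "to", "td", "nt")) {
    assign(f, get(f, envir = e), envir = e2)
  }
  for (f in c("ns_map", "node_map", "doc_map", "trip_map")) {
    assign(f, list2env(as.list(get(f, envir = e), all.names = TRUE),
                       parent = emptyenv()),
           envir = e2)
  }
  e2$idx <- lapply(config, function(l) {
    list(bin = l$bin, sort = l$sort, ord = integer(0), built = 0L)
  })
  e2$txn <- NULL
  new("TripleStore", ptr = e2)
}
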
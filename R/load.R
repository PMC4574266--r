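## Transactional document loading.
##
## All store mutations are appends, so a transaction records (i) the table
## sizes at begin and (ii) every hash-map key added while active. Rollback
## truncates the tables and removes the journalled keys, restoring the store
## bit-for-bit. An import closure (load_file with a catalog) runs inside a
## single transaction: if any document of the closure fails, none of them is
## kept.

.beginTxn <- function(e) {
  e$txn <- list(
    nNs = length(e$ns_pref),
    nNode = length(e$node_kind),
    nDoc = length(e$doc_path),
    nt = e$nt,
    keys = list(ns = new.env(parent = emptyenv()),
                node = new.env(parent = emptyenv()),
                doc = new.env(parent = emptyenv()),
                trip = new.env(parent = emptyenv()))
  )
  invisible(NULL)
}

.commitTxn <- function(e) {
  e$txn <- NULL
  invisible(NULL)
}

.rollbackTxn <- function(e) {
  t <- e$txn
  if (is.null(t)) return(invisible(NULL))
  length(e$ns_pref) <- t$nNs
  length(e$node_kind) <- t$nNode
  length(e$node_i1) <- t$nNode
  length(e$node_i2) <- t$nNode
  length(e$node_c1) <- t$nNode
  length(e$node_c2) <- t$nNode
  length(e$node_pay) <- t$nNode
  length(e$doc_path) <- t$nDoc
  length(e$doc_onto) <- t$nDoc
  length(e$doc_ver) <- t$nDoc
  length(e$doc_blank_n) <- t$nDoc
  e$nt <- t$nt
  rm(list = ls(t$keys$ns, all.names = TRUE), envir = e$ns_map)
  rm(list = ls(t$keys$node, all.names = TRUE), envir = e$node_map)
  rm(list = ls(t$keys$doc, all.names = TRUE), envir = e$doc_map)
  rm(list = ls(t$keys$trip, all.names = TRUE), envir = e$trip_map)
  for (i in seq_along(e$idx)) {
    if (e$idx[[i]]$built > e$nt) e$idx[[i]]$built <- -1L
  }
  e$txn <- NULL
  invisible(NULL)
}

## ---- interpretation of parsed statements ----------------------------------

.OWL_ONTOLOGY <- function() paste0(.NS_OWL, "Ontology")
.OWL_VERSION_IRI <- function() paste0(.NS_OWL, "versionIRI")
.OWL_IMPORTS <- function() paste0(.NS_OWL, "imports")
.RDF_TYPE <- function() paste0(.NS_RDF, "type")

## Stage a parsed statement table into the store under a new DocId.
## Returns list(doc = DocId, imports = character vector of import IRIs).
.stageDocument <- function(e, st, stmts, docPath) {
  if (!is.na(lookupDocument(st, docPath))) {
    stopLoadError("file", sprintf("document already loaded: %s", docPath),
                  path = docPath)
  }

  isHeader <- stmts$p == .RDF_TYPE() & stmts$oKind == "iri" &
    stmts$o == .OWL_ONTOLOGY()
  ontoIri <- NA_character_
  if (any(isHeader)) {
    subs <- unique(stmts$s[isHeader])
    if (length(subs) > 1L || sum(isHeader) > 1L) {
      stopLoadError("owl",
                    sprintf("document contains %d owl:Ontology headers",
                            sum(isHeader)),
                    path = docPath)
    }
    if (stmts$sKind[isHeader][1] != "iri") {
      stopLoadError("owl", "owl:Ontology header subject must be an IRI",
                    path = docPath)
    }
    ontoIri <- subs
  }
  verIri <- NA_character_
  if (!is.na(ontoIri)) {
    isVer <- stmts$s == ontoIri & stmts$p == .OWL_VERSION_IRI() &
      stmts$oKind == "iri"
    if (any(isVer)) verIri <- stmts$o[isVer][1]
  }

  ontoId <- if (is.na(ontoIri)) NA_integer_ else internIri(st, ontoIri)
  verId <- if (is.na(verIri)) NA_integer_ else internIri(st, verIri)
  doc <- registerDocument(st, docPath, ontoId, verId)

  n <- nrow(stmts)
  sId <- integer(n); oId <- integer(n)

  ## IRIs, vectorized over the unique set
  iriStrings <- unique(c(stmts$s[stmts$sKind == "iri"], stmts$p,
                         stmts$o[stmts$oKind == "iri"]))
  iriIds <- internIri(st, iriStrings)
  names(iriIds) <- iriStrings
  pId <- unname(iriIds[stmts$p])
  sIri <- stmts$sKind == "iri"
  oIri <- stmts$oKind == "iri"
  sId[sIri] <- unname(iriIds[stmts$s[sIri]])
  oId[oIri] <- unname(iriIds[stmts$o[oIri]])

  ## blanks, in first-occurrence order across (s, o) in statement order
  labSeq <- as.vector(rbind(ifelse(stmts$sKind == "blank", stmts$s, NA),
                            ifelse(stmts$oKind == "blank", stmts$o, NA)))
  labSeq <- unique(labSeq[!is.na(labSeq)])
  blankIds <- vapply(labSeq, function(l) makeBlank(st, doc, l), integer(1))
  sBlank <- stmts$sKind == "blank"
  oBlank <- stmts$oKind == "blank"
  if (length(labSeq)) {
    sId[sBlank] <- unname(blankIds[stmts$s[sBlank]])
    oId[oBlank] <- unname(blankIds[stmts$o[oBlank]])
  }

  ## literals; a bad lexical form for its datatype is an RDF-level error
  oLit <- which(stmts$oKind == "lit")
  for (i in oLit) {
    dt <- stmts$oDatatype[i]
    oId[i] <- tryCatch(
      internLiteral(st, stmts$o[i],
                    datatype = if (is.na(dt)) NULL else dt,
                    language = stmts$oLang[i]),
      owlstore_literal_parse_error = function(cond) {
        stopLoadError("rdf", conditionMessage(cond), path = docPath)
      }
    )
  }

  .addTriplesRaw(e, sId, pId, oId, rep(doc, n))
  .owlLog("loaded %d statements from %s", n, docPath)

  imports <- character(0)
  if (!is.na(ontoIri)) {
    isImp <- stmts$s == ontoIri & stmts$p == .OWL_IMPORTS() &
      stmts$oKind == "iri"
    imports <- stmts$o[isImp]
  }
  list(doc = doc, imports = imports)
}

## Is an ontology or version IRI already present among loaded documents?
.haveOntology <- function(e, iri) {
  ids <- c(e$doc_onto, e$doc_ver)
  ids <- ids[!is.na(ids)]
  if (!length(ids)) return(FALSE)
  any(vapply(ids, function(i) .iriString(e, i), character(1)) == iri)
}

.loadImports <- function(st, imports, catalog, docPath) {
  e <- st@ptr
  for (imp in imports) {
    if (.haveOntology(e, imp)) next
    path <- tryCatch(
      resolveIri(catalog, imp),
      owlstore_resolution_error = function(cond) {
        stopLoadError("owl",
                      sprintf("cannot resolve owl:imports <%s>", imp),
                      path = docPath)
      }
    )
    if (!is.na(lookupDocument(st, .canonPath(path)))) next
    loadOntologyFile(st, path, catalog)
  }
  invisible(NULL)
}

.canonPath <- function(path) {
  normalizePath(path, winslash = "/", mustWork = FALSE)
}

## ---- public loaders -------------------------------------------------------

#' Load an RDF/XML document from text or a stream
#'
#' Parses the content, registers a document descriptor (the ontology IRI is
#' the subject of the `owl:Ontology` header triple, the version IRI its
#' `owl:versionIRI`, when present), interns all statements and adds the
#' triples under the new DocId. Loading is transactional: on *any* error
#' the store's namespaces, nodes, documents and triples are exactly as
#' before the call.
#'
#' @param store a [TripleStore].
#' @param x RDF/XML content (string, raw vector or connection).
#' @param baseIri base IRI for resolving relative references.
#' @param catalog optional [OntologyCatalog]; when given, the document's
#'   `owl:imports` are resolved and loaded recursively (each document at
#'   most once, cycle-safe) within the same transaction.
#' @param docPath the path the document is registered under; defaults to
#'   `baseIri`.
#' @return the new integer DocId, invisibly for the imported documents.
#' @export
loadRdfXml <- function(store, x, baseIri = "", catalog = NULL,
                       docPath = baseIri) {
  e <- store@ptr
  top <- is.null(e$txn)
  if (top) .beginTxn(e)
  res <- tryCatch({
    stmts <- parseRdfXml(x, baseIri)
    staged <- .stageDocument(e, store, stmts, docPath)
    if (!is.null(catalog)) {
      .loadImports(store, staged$imports, catalog, docPath)
    } else if (length(staged$imports)) {
      .owlLog("ignoring %d owl:imports (no catalog supplied)",
              length(staged$imports))
    }
    staged$doc
  }, error = function(cond) {
    if (top) .rollbackTxn(e)
    stop(cond)
  })
  if (top) .commitTxn(e)
  res
}

#' Load an ontology document from the filesystem
#'
#' As [loadRdfXml()], with the base IRI set to the file IRI
#' (`file://` + absolute path). With a catalog, the whole imports closure
#' is loaded in one transaction.
#'
#' @param store a [TripleStore].
#' @param path path of an RDF/XML ontology document.
#' @param catalog optional [OntologyCatalog] for imports resolution.
#' @return the integer DocId of the loaded document.
#' @export
loadOntologyFile <- function(store, path, catalog = NULL) {
  if (!file.exists(path) || dir.exists(path)) {
    stopLoadError("file", sprintf("cannot read file: %s", path), path = path)
  }
  bytes <- tryCatch(
    readBin(path, "raw", file.info(path)$size),
    error = function(cond) {
      stopLoadError("file", conditionMessage(cond), path = path)
    }
  )
  abs <- .canonPath(path)
  loadRdfXml(store, bytes, baseIri = paste0("file://", abs),
             catalog = catalog, docPath = abs)
}
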
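## RDF/XML interpretation.
##
## XML parsing (well-formedness, encodings, namespace resolution) is done by
## xml2/libxml2; this file implements the RDF/XML "striping" interpretation
## on top of the DOM: alternating node elements and property elements, the
## rdf:about / rdf:ID / rdf:nodeID subject forms, property attributes,
## rdf:parseType Resource / Collection / Literal, xml:base and xml:lang
## scoping, and rdf:li numbering. The result is a flat statement table in
## document order; nothing touches a store (see load.R for that).

.RDF_SYNTAX_ATTRS <- c("rdf:about", "rdf:ID", "rdf:nodeID", "rdf:resource",
                       "rdf:datatype", "rdf:parseType")
.RDF_OBSOLETE_ATTRS <- c("rdf:aboutEach", "rdf:aboutEachPrefix", "rdf:bagID")
.RDF_NONELEMENT <- c("RDF", "ID", "about", "nodeID", "resource", "datatype",
                     "parseType", "aboutEach", "aboutEachPrefix", "bagID")

.rdfIri <- function(frag) paste0(.NS_RDF, frag)

.xmlLoc <- function(el) tryCatch(xml2::xml_path(el), error = function(e) NA)

.rdfErr <- function(msg, el = NULL) {
  stopLoadError("rdf", msg, location = if (!is.null(el)) .xmlLoc(el))
}

## Parser context: namespace map, statement accumulator, counters.
.newRdfCtx <- function(doc) {
  ns <- xml2::xml_ns(doc)
  map <- as.character(ns)
  names(map) <- names(ns)
  map[["xml"]] <- .NS_XML
  ctx <- new.env(parent = emptyenv())
  ctx$ns <- map
  ctx$nsObj <- structure(unname(map), names = names(map),
                         class = "xml_namespace")
  ctx$stmts <- vector("list", 64L)
  ctx$nst <- 0L
  ctx$bcount <- 0L
  ctx$idSeen <- new.env(parent = emptyenv())
  ctx
}

.expandQName <- function(ctx, qname, el, what) {
  i <- regexpr(":", qname, fixed = TRUE)
  if (i < 0L) {
    .rdfErr(sprintf("%s '%s' has no XML namespace", what, qname), el)
  }
  pfx <- substr(qname, 1L, i - 1L)
  local <- substring(qname, i + 1L)
  uri <- ctx$ns[[pfx]]
  if (is.null(uri)) {
    .rdfErr(sprintf("undeclared namespace prefix in %s '%s'", what, qname), el)
  }
  paste0(uri, local)
}

.emit <- function(ctx, s, sk, p, o, ok, dt = NA_character_, lang = "") {
  i <- ctx$nst + 1L
  if (i > length(ctx$stmts)) length(ctx$stmts) <- 2L * length(ctx$stmts)
  ctx$stmts[[i]] <- list(s = s, sk = sk, p = p, o = o, ok = ok,
                         dt = dt, lang = lang)
  ctx$nst <- i
}

.freshBlank <- function(ctx) {
  ctx$bcount <- ctx$bcount + 1L
  paste0(".g", ctx$bcount)
}

.resolveIriRef <- function(ctx, ref, base, el) {
  if (.isAbsoluteIri(ref)) return(ref)
  if (is.na(base) || !nzchar(base)) {
    .rdfErr(sprintf("relative IRI reference '%s' with no base IRI", ref), el)
  }
  out <- xml2::url_absolute(ref, base)
  if (is.na(out) || !nzchar(out)) {
    .rdfErr(sprintf("cannot resolve IRI reference '%s'", ref), el)
  }
  out
}

.checkNCName <- function(val, what, el) {
  if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", val)) {
    .rdfErr(sprintf("%s '%s' is not a valid name", what, val), el)
  }
  val
}

## expanded attribute table of an element: names are qnames per ctx$ns
.attrTable <- function(ctx, el) {
  at <- xml2::xml_attrs(el, ctx$nsObj)
  if (!length(at)) return(at)
  bad <- .RDF_OBSOLETE_ATTRS[.RDF_OBSOLETE_ATTRS %in% names(at)]
  if (length(bad)) {
    .rdfErr(sprintf("obsolete RDF/XML attribute %s", bad[1]), el)
  }
  at
}

.updateBaseLang <- function(ctx, at, base, lang, el) {
  if ("xml:base" %in% names(at)) {
    b <- at[["xml:base"]]
    base <- if (.isAbsoluteIri(b)) b else .resolveIriRef(ctx, b, base, el)
    base <- sub("#.*$", "", base)
  }
  if ("xml:lang" %in% names(at)) lang <- at[["xml:lang"]]
  list(base = base, lang = lang)
}

## qnames of attributes that are property attributes (not syntax, not xml:*)
.propertyAttrNames <- function(at) {
  nm <- names(at)
  nm[!(nm %in% .RDF_SYNTAX_ATTRS) & !startsWith(nm, "xml:") & nm != "xml"]
}

.elementChildren <- function(el) {
  kids <- xml2::xml_contents(el)
  keep <- logical(length(kids))
  for (i in seq_along(kids)) {
    t <- xml2::xml_type(kids[[i]])
    if (t == "element") {
      keep[i] <- TRUE
    } else if (t == "text" || t == "cdata") {
      if (grepl("[^[:space:]]", xml2::xml_text(kids[[i]]))) {
        .rdfErr("unexpected text content between elements", el)
      }
    }
  }
  kids[keep]
}

## ---- node elements --------------------------------------------------------

## Interprets a node element; emits its statements and returns the subject
## as list(ref = label-or-iri, kind = "iri"|"blank").
.nodeElement <- function(ctx, el, base, lang) {
  at <- .attrTable(ctx, el)
  bl <- .updateBaseLang(ctx, at, base, lang, el)
  base <- bl$base; lang <- bl$lang

  name <- .expandQName(ctx, xml2::xml_name(el, ctx$nsObj), el, "element")
  if (startsWith(name, .NS_RDF)) {
    local <- substring(name, nchar(.NS_RDF) + 1L)
    if (local %in% .RDF_NONELEMENT || local == "li") {
      .rdfErr(sprintf("rdf:%s cannot be used as a node element", local), el)
    }
  }

  nSubjAttrs <- sum(c("rdf:about", "rdf:ID", "rdf:nodeID") %in% names(at))
  if (nSubjAttrs > 1L) {
    .rdfErr("at most one of rdf:about, rdf:ID, rdf:nodeID is allowed", el)
  }
  if ("rdf:about" %in% names(at)) {
    subj <- .resolveIriRef(ctx, at[["rdf:about"]], base, el)
    sk <- "iri"
  } else if ("rdf:ID" %in% names(at)) {
    id <- .checkNCName(at[["rdf:ID"]], "rdf:ID", el)
    subj <- .resolveIriRef(ctx, paste0("#", id), base, el)
    if (!is.null(get0(subj, envir = ctx$idSeen, inherits = FALSE))) {
      .rdfErr(sprintf("rdf:ID '%s' is used more than once", id), el)
    }
    assign(subj, TRUE, envir = ctx$idSeen)
    sk <- "iri"
  } else if ("rdf:nodeID" %in% names(at)) {
    subj <- .checkNCName(at[["rdf:nodeID"]], "rdf:nodeID", el)
    sk <- "blank"
  } else {
    subj <- .freshBlank(ctx)
    sk <- "blank"
  }

  if (name != .rdfIri("Description")) {
    .emit(ctx, subj, sk, .rdfIri("type"), name, "iri")
  }

  for (anm in .propertyAttrNames(at)) {
    aIri <- .expandQName(ctx, anm, el, "attribute")
    if (aIri == .rdfIri("type")) {
      .emit(ctx, subj, sk, aIri, .resolveIriRef(ctx, at[[anm]], base, el), "iri")
    } else {
      .emit(ctx, subj, sk, aIri, at[[anm]], "lit", lang = lang)
    }
  }

  liCounter <- new.env(parent = emptyenv())
  liCounter$n <- 0L
  for (child in .elementChildren(el)) {
    .propertyElement(ctx, child, subj, sk, base, lang, liCounter)
  }
  list(ref = subj, kind = sk)
}

## ---- property elements ----------------------------------------------------

.propertyElement <- function(ctx, el, subj, sk, base, lang, liCounter) {
  at <- .attrTable(ctx, el)
  bl <- .updateBaseLang(ctx, at, base, lang, el)
  base <- bl$base; lang <- bl$lang

  name <- .expandQName(ctx, xml2::xml_name(el, ctx$nsObj), el, "element")
  if (name == .rdfIri("li")) {
    liCounter$n <- liCounter$n + 1L
    pred <- .rdfIri(paste0("_", liCounter$n))
  } else {
    pred <- name
    if (startsWith(name, .NS_RDF)) {
      local <- substring(name, nchar(.NS_RDF) + 1L)
      if (local %in% .RDF_NONELEMENT || local == "Description") {
        .rdfErr(sprintf("rdf:%s cannot be used as a property element", local), el)
      }
    }
  }

  reifyIri <- NULL
  if ("rdf:ID" %in% names(at)) {
    id <- .checkNCName(at[["rdf:ID"]], "rdf:ID", el)
    reifyIri <- .resolveIriRef(ctx, paste0("#", id), base, el)
    if (!is.null(get0(reifyIri, envir = ctx$idSeen, inherits = FALSE))) {
      .rdfErr(sprintf("rdf:ID '%s' is used more than once", id), el)
    }
    assign(reifyIri, TRUE, envir = ctx$idSeen)
  }

  emitMain <- function(o, ok, dt = NA_character_, olang = "") {
    .emit(ctx, subj, sk, pred, o, ok, dt, olang)
    if (!is.null(reifyIri)) {
      .emit(ctx, reifyIri, "iri", .rdfIri("type"), .rdfIri("Statement"), "iri")
      .emit(ctx, reifyIri, "iri", .rdfIri("subject"), subj,
            if (sk == "blank") "blank" else "iri")
      .emit(ctx, reifyIri, "iri", .rdfIri("predicate"), pred, "iri")
      .emit(ctx, reifyIri, "iri", .rdfIri("object"), o, ok, dt, olang)
    }
  }

  propAttrs <- .propertyAttrNames(at)
  hasResource <- "rdf:resource" %in% names(at)
  hasNodeId <- "rdf:nodeID" %in% names(at)
  hasDatatype <- "rdf:datatype" %in% names(at)
  parseType <- if ("rdf:parseType" %in% names(at)) at[["rdf:parseType"]] else NA

  if (hasResource && hasNodeId) {
    .rdfErr("rdf:resource and rdf:nodeID cannot be combined", el)
  }
  if (!is.na(parseType) && (hasResource || hasNodeId || hasDatatype)) {
    .rdfErr("rdf:parseType cannot be combined with rdf:resource/nodeID/datatype", el)
  }

  kids <- xml2::xml_contents(el)
  kinds <- vapply(seq_along(kids), function(i)
    as.character(xml2::xml_type(kids[[i]])), character(1))
  elKids <- kids[kinds == "element"]
  ## direct text content only: descendants of nested node elements are theirs
  text <- paste(vapply(which(kinds %in% c("text", "cdata")), function(i)
    xml2::xml_text(kids[[i]]), character(1)), collapse = "")
  hasText <- grepl("[^[:space:]]", text)

  if (!is.na(parseType)) {
    if (parseType == "Resource") {
      b <- .freshBlank(ctx)
      emitMain(b, "blank")
      liC <- new.env(parent = emptyenv()); liC$n <- 0L
      for (child in .elementChildren(el)) {
        .propertyElement(ctx, child, b, "blank", base, lang, liC)
      }
    } else if (parseType == "Collection") {
      members <- list()
      for (child in .elementChildren(el)) {
        members[[length(members) + 1L]] <- .nodeElement(ctx, child, base, lang)
      }
      k <- length(members)
      if (k == 0L) {
        emitMain(.rdfIri("nil"), "iri")
      } else {
        cells <- vapply(seq_len(k), function(i) .freshBlank(ctx), character(1))
        emitMain(cells[1], "blank")
        for (i in seq_len(k)) {
          m <- members[[i]]
          .emit(ctx, cells[i], "blank", .rdfIri("first"), m$ref, m$kind)
          nxt <- if (i < k) list(ref = cells[i + 1], kind = "blank")
                 else list(ref = .rdfIri("nil"), kind = "iri")
          .emit(ctx, cells[i], "blank", .rdfIri("rest"), nxt$ref, nxt$kind)
        }
      }
    } else if (parseType == "Literal") {
      raw <- paste(vapply(seq_along(kids), function(i)
        as.character(kids[[i]]), character(1)), collapse = "")
      emitMain(raw, "lit", dt = .rdfIri("XMLLiteral"))
    } else {
      .rdfErr(sprintf("unknown rdf:parseType '%s'", parseType), el)
    }
    return(invisible(NULL))
  }

  if (hasResource || hasNodeId || length(propAttrs)) {
    if (length(elKids) || hasText) {
      .rdfErr("property element with object attributes must be empty", el)
    }
    if (hasResource) {
      obj <- .resolveIriRef(ctx, at[["rdf:resource"]], base, el)
      ok <- "iri"
    } else if (hasNodeId) {
      obj <- .checkNCName(at[["rdf:nodeID"]], "rdf:nodeID", el)
      ok <- "blank"
    } else {
      obj <- .freshBlank(ctx)
      ok <- "blank"
    }
    emitMain(obj, ok)
    for (anm in propAttrs) {
      aIri <- .expandQName(ctx, anm, el, "attribute")
      if (aIri == .rdfIri("type")) {
        .emit(ctx, obj, ok, aIri, .resolveIriRef(ctx, at[[anm]], base, el), "iri")
      } else {
        .emit(ctx, obj, ok, aIri, at[[anm]], "lit", lang = lang)
      }
    }
    return(invisible(NULL))
  }

  if (length(elKids)) {
    if (length(elKids) > 1L) {
      .rdfErr("property element contains more than one node element", el)
    }
    if (hasText) {
      .rdfErr("property element mixes text and element content", el)
    }
    obj <- .nodeElement(ctx, elKids[[1]], base, lang)
    emitMain(obj$ref, obj$kind)
    return(invisible(NULL))
  }

  ## literal content (possibly empty)
  if (hasDatatype) {
    dtIri <- .resolveIriRef(ctx, at[["rdf:datatype"]], base, el)
    emitMain(text, "lit", dt = dtIri)
  } else {
    emitMain(text, "lit", olang = lang)
  }
  invisible(NULL)
}

## ---- entry point ----------------------------------------------------------

#' Parse an RDF/XML document into raw statements
#'
#' A pure function: parses the bytes and returns the statements in document
#' order without touching any store. Supports node elements (typed and
#' `rdf:Description`), `rdf:about` / `rdf:ID` / `rdf:nodeID`, property
#' elements with `rdf:resource` / `rdf:nodeID` / `rdf:datatype` /
#' `xml:lang`, nested node elements, property attributes,
#' `rdf:parseType="Resource"`, `"Collection"` and `"Literal"`, `rdf:li`,
#' reification via `rdf:ID` on property elements, and `xml:base` relative
#' IRI resolution.
#'
#' @param x RDF/XML content: a string, raw vector, file path or connection
#'   accepted by [xml2::read_xml()].
#' @param baseIri base IRI used to resolve relative IRI references.
#' @return a data.frame with columns `s`, `sKind` (`"iri"`/`"blank"`), `p`,
#'   `o`, `oKind` (`"iri"`/`"blank"`/`"lit"`), `oDatatype` (IRI or `NA` for
#'   plain literals), `oLang`. Generated blank labels start with `".g"`;
#'   labels from `rdf:nodeID` are kept verbatim.
#' @examples
#' parseRdfXml(paste0(
#'   '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
#'   ' xmlns:owl="http://www.w3.org/2002/07/owl#">',
#'   '<owl:Class rdf:about="http://example.org/A"/></rdf:RDF>'),
#'   baseIri = "http://example.org/")
#' @export
parseRdfXml <- function(x, baseIri = "") {
  doc <- tryCatch(
    suppressWarnings(xml2::read_xml(x)),
    error = function(e) {
      stopLoadError("xml", conditionMessage(e))
    }
  )
  ctx <- .newRdfCtx(doc)
  root <- xml2::xml_root(doc)
  rootName <- tryCatch(
    .expandQName(ctx, xml2::xml_name(root, ctx$nsObj), root, "element"),
    error = function(e) NA_character_)
  base <- if (nzchar(baseIri)) baseIri else NA_character_
  if (!is.na(rootName) && rootName == .rdfIri("RDF")) {
    at <- .attrTable(ctx, root)
    bl <- .updateBaseLang(ctx, at, base, "", root)
    for (child in .elementChildren(root)) {
      .nodeElement(ctx, child, bl$base, bl$lang)
    }
  } else {
    .nodeElement(ctx, root, base, "")
  }
  n <- ctx$nst
  sts <- ctx$stmts[seq_len(n)]
  data.frame(
    s = vapply(sts, `[[`, character(1), "s"),
    sKind = vapply(sts, `[[`, character(1), "sk"),
    p = vapply(sts, `[[`, character(1), "p"),
    o = vapply(sts, `[[`, character(1), "o"),
    oKind = vapply(sts, `[[`, character(1), "ok"),
    oDatatype = vapply(sts, `[[`, character(1), "dt"),
    oLang = vapply(sts, `[[`, character(1), "lang"),
    stringsAsFactors = FALSE
  )
}
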
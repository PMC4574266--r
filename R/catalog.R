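## Filesystem catalog of ontology documents.

#' Build a catalog by scanning a directory for ontology documents
#'
#' Every readable file whose content yields an `owl:Ontology` header is
#' entered into the catalog with its ontology IRI and (when present)
#' version IRI. Only the header is interpreted, so arbitrary body content
#' never causes a scan failure; files that are not well-formed XML or carry
#' no header are skipped with a logged warning (enable
#' `options(owlstore.verbose = TRUE)` to see them). Files with the
#' conventional extensions `.owl`, `.rdf`, `.xml` are tried first, then the
#' rest.
#'
#' @param root directory to scan.
#' @param recurse whether to descend into subdirectories.
#' @return an [OntologyCatalog].
#' @export
scanOntologyDir <- function(root, recurse = TRUE) {
  if (!dir.exists(root)) {
    stopLoadError("file", sprintf("no such directory: %s", root), path = root)
  }
  files <- list.files(root, recursive = recurse, full.names = TRUE)
  files <- files[!dir.exists(files)]
  pref <- grepl("\\.(owl|rdf|xml)$", files, ignore.case = TRUE)
  files <- c(sort(files[pref]), sort(files[!pref]))
  rows <- lapply(files, function(f) {
    hdr <- .ontologyHeader(f)
    if (is.null(hdr)) return(NULL)
    data.frame(path = .canonPath(f), ontology_iri = hdr$ontology,
               version_iri = hdr$version, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(path = character(0), ontology_iri = character(0),
               version_iri = character(0), stringsAsFactors = FALSE)
  }
  new("OntologyCatalog", entries = entries)
}

## Shallow header extraction: parse the XML and read only the owl:Ontology
## node, its rdf:about and owl:versionIRI. Returns NULL when the file is
## not usable as an ontology document.
.ontologyHeader <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) NULL)
  if (is.null(doc)) {
    .owlLog("catalog: skipping %s (not well-formed XML)", path)
    return(NULL)
  }
  nsSpec <- c(rdf = .NS_RDF, owl = .NS_OWL)
  node <- tryCatch(
    xml2::xml_find_first(doc, "//owl:Ontology[@rdf:about]", nsSpec),
    error = function(e) NULL)
  about <- NULL
  if (!is.null(node) && !inherits(node, "xml_missing")) {
    about <- xml2::xml_attr(node, "rdf:about", nsSpec)
  } else {
    ## rdf:Description form: <rdf:Description rdf:about=...>
    ##   <rdf:type rdf:resource="...owl#Ontology"/>
    node <- tryCatch(xml2::xml_find_first(
      doc,
      sprintf("//rdf:Description[rdf:type/@rdf:resource='%sOntology']",
              .NS_OWL),
      nsSpec), error = function(e) NULL)
    if (!is.null(node) && !inherits(node, "xml_missing")) {
      about <- xml2::xml_attr(node, "rdf:about", nsSpec)
    }
  }
  if (is.null(about) || is.na(about) || !.isAbsoluteIri(about)) {
    .owlLog("catalog: skipping %s (no owl:Ontology header)", path)
    return(NULL)
  }
  ver <- NA_character_
  vnode <- xml2::xml_find_first(node, "./owl:versionIRI", nsSpec)
  if (!inherits(vnode, "xml_missing")) {
    v <- xml2::xml_attr(vnode, "rdf:resource", nsSpec)
    if (!is.na(v)) ver <- v
  }
  list(ontology = about, version = ver)
}

#' Resolve an IRI against a catalog
#'
#' An exact version-IRI match is preferred; otherwise the IRI is matched
#' against ontology IRIs. When several files share the ontology IRI with
#' distinct version IRIs, the lexicographically greatest version IRI wins
#' (a documented heuristic standing in for "latest version"); an absent
#' version IRI sorts lowest.
#'
#' @param catalog an [OntologyCatalog].
#' @param iri the ontology or version IRI to resolve.
#' @return the filesystem path of the matching document.
#' @export
resolveIri <- function(catalog, iri) {
  en <- catalog@entries
  hit <- en[!is.na(en$version_iri) & en$version_iri == iri, , drop = FALSE]
  if (nrow(hit)) {
    return(sort(hit$path, method = "radix")[1])
  }
  hit <- en[en$ontology_iri == iri, , drop = FALSE]
  if (nrow(hit)) {
    key <- ifelse(is.na(hit$version_iri), "", hit$version_iri)
    ord <- order(key, hit$path, method = "radix", decreasing = c(TRUE, FALSE))
    return(hit$path[ord][1])
  }
  stopResolutionError(iri)
}

#' @describeIn resolveIri number of catalog entries
#' @export
catalogSize <- function(catalog) nrow(catalog@entries)

#' @describeIn resolveIri the entry table (path, ontology_iri, version_iri)
#' @export
catalogEntries <- function(catalog) catalog@entries

setMethod("show", "OntologyCatalog", function(object) {
  cat(sprintf("OntologyCatalog with %d entries\n", nrow(object@entries)))
  if (nrow(object@entries)) {
    utils::head(object@entries, 5L)
    print(utils::head(object@entries, 5L), row.names = FALSE)
  }
})
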
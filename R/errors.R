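## Condition classes used across the package.
##
## All errors signalled by owlstore inherit from "owlstore_error". Loading
## errors additionally carry a `stage` field ("file", "xml", "rdf" or "owl"),
## mirroring the level of the loading pipeline at which the problem was
## detected; raising one guarantees the target store was left unchanged.

.owlCondition <- function(class, message, ...) {
  structure(
    class = c(class, "owlstore_error", "error", "condition"),
    list(message = message, call = sys.call(-2L), ...)
  )
}

stopValueError <- function(message) {
  stop(.owlCondition("owlstore_value_error", message))
}

stopLookupError <- function(message) {
  stop(.owlCondition("owlstore_lookup_error", message))
}

stopConfigError <- function(message) {
  stop(.owlCondition("owlstore_config_error", message))
}

stopLiteralParseError <- function(lexical, datatype) {
  stop(.owlCondition(
    c("owlstore_literal_parse_error", "owlstore_value_error"),
    sprintf("cannot parse literal %s for datatype <%s>",
            deparse(lexical), datatype),
    lexical = lexical, datatype = datatype
  ))
}

stopLoadError <- function(stage, message, path = NULL, location = NULL) {
  loc <- character(0)
  if (!is.null(path)) loc <- c(loc, path)
  if (!is.null(location)) loc <- c(loc, location)
  full <- if (length(loc)) {
    sprintf("[%s] %s (%s)", stage, message, paste(loc, collapse = ", "))
  } else {
    sprintf("[%s] %s", stage, message)
  }
  stop(.owlCondition("owlstore_load_error", full,
                     stage = stage, path = path, location = location))
}

stopMappingError <- function(message, class = character(0)) {
  stop(.owlCondition(c(class, "owlstore_mapping_error"), message))
}

stopResolutionError <- function(iri) {
  stop(.owlCondition("owlstore_resolution_error",
                     sprintf("cannot resolve IRI <%s> against catalog", iri),
                     iri = iri))
}

#' Stage of a load error
#'
#' Loading an ontology document can fail at four levels: opening the file
#' (`"file"`), parsing the XML (`"xml"`), interpreting the XML as RDF
#' (`"rdf"`), or interpreting the RDF as OWL (`"owl"`). Every load failure
#' carries the stage at which it was detected.
#'
#' @param e a condition object signalled by [loadOntologyFile()] or
#'   [loadRdfXml()].
#' @return a single character string, or `NA_character_` if `e` is not a
#'   load error.
#' @export
loadErrorStage <- function(e) {
  if (inherits(e, "owlstore_load_error")) e$stage else NA_character_
}

.owlLog <- function(...) {
  if (isTRUE(getOption("owlstore.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}
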
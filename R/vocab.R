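## Standard RDF / RDFS / OWL 2 / XSD vocabulary.
##
## The four standard namespaces and their terms are interned into every fresh
## store, in the fixed order of the tables below, before any user content.
## Their NsId / NodeId values are therefore constants: identical across all
## store instances and across runs, which is what lets code refer to e.g.
## owl:Class by a plain integer.

.NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
.NS_OWL  <- "http://www.w3.org/2002/07/owl#"
.NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"
.NS_XML  <- "http://www.w3.org/XML/1998/namespace"

.VOCAB_TERMS <- list(
  rdf = c(
    "type", "Property", "XMLLiteral", "PlainLiteral", "langString",
    "first", "rest", "nil", "List", "Statement", "subject", "predicate",
    "object", "value", "Bag", "Seq", "Alt", "HTML"
  ),
  rdfs = c(
    "Resource", "Class", "Literal", "Datatype", "subClassOf",
    "subPropertyOf", "domain", "range", "label", "comment", "seeAlso",
    "isDefinedBy", "member", "Container", "ContainerMembershipProperty"
  ),
  owl = c(
    "Ontology", "imports", "versionIRI", "versionInfo", "Class",
    "Restriction", "Thing", "Nothing", "ObjectProperty", "DatatypeProperty",
    "AnnotationProperty", "NamedIndividual", "FunctionalProperty",
    "InverseFunctionalProperty", "TransitiveProperty", "SymmetricProperty",
    "AsymmetricProperty", "ReflexiveProperty", "IrreflexiveProperty",
    "inverseOf", "equivalentClass", "equivalentProperty", "disjointWith",
    "propertyDisjointWith", "intersectionOf", "unionOf", "complementOf",
    "oneOf", "onProperty", "someValuesFrom", "allValuesFrom", "hasValue",
    "hasSelf", "minCardinality", "maxCardinality", "cardinality",
    "minQualifiedCardinality", "maxQualifiedCardinality",
    "qualifiedCardinality", "onClass", "onDataRange", "onDatatype",
    "withRestrictions", "datatypeComplementOf", "propertyChainAxiom",
    "hasKey", "disjointUnionOf", "AllDifferent", "AllDisjointClasses",
    "AllDisjointProperties", "distinctMembers", "members",
    "NegativePropertyAssertion", "sourceIndividual", "assertionProperty",
    "targetIndividual", "targetValue", "Axiom", "annotatedSource",
    "annotatedProperty", "annotatedTarget", "Annotation", "deprecated",
    "DeprecatedClass", "DeprecatedProperty", "backwardCompatibleWith",
    "incompatibleWith", "priorVersion", "OntologyProperty", "sameAs",
    "differentFrom", "topObjectProperty", "bottomObjectProperty",
    "topDataProperty", "bottomDataProperty", "rational", "real"
  ),
  xsd = c(
    "string", "boolean", "decimal", "integer", "float", "double",
    "dateTime", "date", "time", "duration", "gYear", "gMonth", "gDay",
    "gYearMonth", "gMonthDay", "hexBinary", "base64Binary", "anyURI",
    "QName", "normalizedString", "token", "language", "NMTOKEN", "Name",
    "NCName", "long", "int", "short", "byte", "nonNegativeInteger",
    "positiveInteger", "nonPositiveInteger", "negativeInteger",
    "unsignedLong", "unsignedInt", "unsignedShort", "unsignedByte",
    "dateTimeStamp", "minInclusive", "maxInclusive", "minExclusive",
    "maxExclusive", "minLength", "maxLength", "length", "pattern"
  )
)

.VOCAB_NS <- c(rdf = .NS_RDF, rdfs = .NS_RDFS, owl = .NS_OWL, xsd = .NS_XSD)

## Full IRIs of all standard terms, in interning order.
.vocabTable <- local({
  pfx <- rep(names(.VOCAB_TERMS), lengths(.VOCAB_TERMS))
  frag <- unlist(.VOCAB_TERMS, use.names = FALSE)
  data.frame(
    prefix = pfx,
    ns = unname(.VOCAB_NS[pfx]),
    fragment = frag,
    iri = paste0(unname(.VOCAB_NS[pfx]), frag),
    stringsAsFactors = FALSE
  )
})

## qname ("owl:Class") -> constant NodeId; populated in .onLoad order:
## terms get NodeIds 1..K in table order, namespaces NsIds 1..4.
.vocabEnv <- new.env(parent = emptyenv())

.initVocabEnv <- function() {
  ids <- seq_len(nrow(.vocabTable))
  qn <- paste0(.vocabTable$prefix, ":", .vocabTable$fragment)
  for (i in ids) {
    assign(qn[i], ids[i], envir = .vocabEnv)
    assign(.vocabTable$iri[i], ids[i], envir = .vocabEnv)
  }
  assign(".count", nrow(.vocabTable), envir = .vocabEnv)
  invisible(NULL)
}

#' Constant NodeId of a standard vocabulary term
#'
#' Terms of the RDF, RDFS, OWL 2 and XSD vocabularies are pre-interned into
#' every [TripleStore] in a fixed order, so their integer NodeIds are
#' compile-time-style constants, identical across stores and runs.
#'
#' @param name a qualified name using the conventional prefixes
#'   (`"owl:Class"`, `"rdf:type"`, ...) or a full IRI.
#' @return the integer NodeId the term has in every store.
#' @examples
#' vocabId("owl:Class")
#' vocabId("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
#' @export
vocabId <- function(name) {
  id <- get0(name, envir = .vocabEnv, inherits = FALSE)
  if (is.null(id)) stopLookupError(sprintf("not a standard vocabulary term: %s", name))
  id
}

.vocabCount <- function() get(".count", envir = .vocabEnv)

.onLoad <- function(libname, pkgname) {
  .initVocabEnv()
}

## Is `fragment` a member of the standard vocabulary of namespace `nsIri`?
## rdf:_1, rdf:_2, ... (container membership) form an infinite valid family.
.isStdTerm <- function(nsIri, fragment) {
  pfx <- names(.VOCAB_NS)[match(nsIri, .VOCAB_NS)]
  if (is.na(pfx)) return(TRUE)  # not a standard namespace
  if (fragment %in% .VOCAB_TERMS[[pfx]]) return(TRUE)
  pfx == "rdf" && grepl("^_[1-9][0-9]*$", fragment)
}

.isStdNamespace <- function(nsIri) nsIri %in% .VOCAB_NS
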
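test_that("loading a generated fixture adds the expected counts", {
  spec <- ontologySpec(nClasses = 5L, nObjectProperties = 1L,
                       nSubclassLinks = 4L, nRestrictions = 2L,
                       nAnnotations = 2L, seed = 3L)
  g <- generateOntologyDocument(spec)
  st <- TripleStore()
  t0 <- tripleCount(st)
  doc <- loadRdfXml(st, g$xml, baseIri = g$ontologyIri)
  expect_equal(tripleCount(st) - t0, g$counts$statements)
  expect_equal(documentCount(st), 1L)
  meta <- getDocument(st, doc)
  expect_identical(meta@ontologyIri, g$ontologyIri)
})

test_that("a failed load leaves the store exactly unchanged", {
  st <- TripleStore()
  ok <- generateOntologyDocument(ontologySpec(nClasses = 4L, seed = 10L,
                                              nSubclassLinks = 3L))
  loadRdfXml(st, ok$xml, baseIri = ok$ontologyIri)
  before <- storeSnapshot(st)
  for (inj in c("xml", "rdf", "owl_header")) {
    bad <- generateOntologyDocument(
      ontologySpec(nClasses = 6L, nObjectProperties = 1L,
                   nSubclassLinks = 5L, nRestrictions = 2L,
                   errorInjection = inj, seed = 11L))
    err <- tryCatch(loadRdfXml(st, bad$xml, baseIri = bad$ontologyIri),
                    owlstore_load_error = identity)
    expect_s3_class(err, "owlstore_load_error")
    expect_identical(loadErrorStage(err), bad$expectedError$stage)
    expect_identical(storeSnapshot(st), before)
  }
})

test_that("blank nodes from different documents never collide", {
  spec <- ontologySpec(nClasses = 4L, nObjectProperties = 1L,
                       nSubclassLinks = 0L, nRestrictions = 3L, seed = 5L)
  g <- generateOntologyDocument(spec)
  st <- TripleStore()
  d1 <- loadRdfXml(st, g$xml, baseIri = g$ontologyIri, docPath = "mem:a")
  d2 <- loadRdfXml(st, g$xml, baseIri = g$ontologyIri, docPath = "mem:b")
  e <- st@ptr
  blanks <- which(e$node_kind == owlstore:::.KIND_BLANK)
  expect_equal(length(blanks), 2L * g$counts$blanks)
  expect_setequal(e$node_i1[blanks], c(d1, d2))
})

test_that("re-loading the same document path is a file-stage error", {
  g <- generateOntologyDocument(ontologySpec(nClasses = 2L,
                                             nSubclassLinks = 0L, seed = 2L))
  st <- TripleStore()
  loadRdfXml(st, g$xml, baseIri = g$ontologyIri, docPath = "mem:x")
  err <- tryCatch(loadRdfXml(st, g$xml, baseIri = g$ontologyIri,
                             docPath = "mem:x"),
                  owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "file")
})

test_that("a document without an ontology header is registered with an absent IRI", {
  xml <- paste0(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '<owl:Class rdf:about="http://ex.org/A"/></rdf:RDF>')
  st <- TripleStore()
  doc <- loadRdfXml(st, xml, baseIri = "http://ex.org/")
  expect_true(is.na(getDocument(st, doc)@ontologyIri))
  expect_equal(tripleCount(st), 1L)
})

writeImportFixture <- function(dir, name, iri, imports = character(0),
                               version = NULL) {
  lines <- c(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
    sprintf('  <owl:Ontology rdf:about="%s">', iri),
    if (!is.null(version))
      sprintf('    <owl:versionIRI rdf:resource="%s"/>', version),
    sprintf('    <owl:imports rdf:resource="%s"/>', imports),
    '  </owl:Ontology>',
    sprintf('  <owl:Class rdf:about="%s#C"/>', iri),
    '</rdf:RDF>')
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

test_that("imports are resolved through the catalog, cycle-safely", {
  dir <- withr::local_tempdir()
  writeImportFixture(dir, "a.owl", "http://ex.org/ontoA",
                     imports = "http://ex.org/ontoB")
  writeImportFixture(dir, "b.owl", "http://ex.org/ontoB",
                     imports = "http://ex.org/ontoA")  # cycle back to A
  ctlg <- scanOntologyDir(dir)
  st <- TripleStore()
  loadOntologyFile(st, file.path(dir, "a.owl"), ctlg)
  expect_equal(documentCount(st), 2L)  # each loaded exactly once
  # without a catalog, imports are ignored
  st2 <- TripleStore()
  loadOntologyFile(st2, file.path(dir, "a.owl"))
  expect_equal(documentCount(st2), 1L)
})

test_that("an unresolvable import aborts and rolls back the whole closure", {
  dir <- withr::local_tempdir()
  writeImportFixture(dir, "a.owl", "http://ex.org/ontoA",
                     imports = c("http://ex.org/ontoB",
                                 "http://ex.org/missing"))
  writeImportFixture(dir, "b.owl", "http://ex.org/ontoB")
  ctlg <- scanOntologyDir(dir)
  st <- TripleStore()
  before <- storeSnapshot(st)
  err <- tryCatch(loadOntologyFile(st, file.path(dir, "a.owl"), ctlg),
                  owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "owl")
  expect_match(conditionMessage(err), "http://ex.org/missing", fixed = TRUE)
  expect_identical(storeSnapshot(st), before)
})

test_that("a deeper import chain loads the reachable set exactly once each", {
  dir <- withr::local_tempdir()
  writeImportFixture(dir, "a.owl", "http://ex.org/iA",
                     imports = c("http://ex.org/iB", "http://ex.org/iC"))
  writeImportFixture(dir, "b.owl", "http://ex.org/iB",
                     imports = "http://ex.org/iC")
  writeImportFixture(dir, "c.owl", "http://ex.org/iC")
  writeImportFixture(dir, "d.owl", "http://ex.org/iD")  # unreachable
  ctlg <- scanOntologyDir(dir)
  st <- TripleStore()
  loadOntologyFile(st, file.path(dir, "a.owl"), ctlg)
  expect_equal(documentCount(st), 3L)
  paths <- vapply(1:3, function(i) getDocument(st, i)@path, character(1))
  expect_false(any(grepl("d\\.owl$", paths)))
})

test_that("missing files are file-stage errors", {
  st <- TripleStore()
  err <- tryCatch(loadOntologyFile(st, "/no/such/file.owl"),
                  owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "file")
})

test_that("loading the same bytes into two fresh stores is fully deterministic", {
  g <- generateOntologyDocument(
    ontologySpec(nClasses = 8L, nObjectProperties = 2L, nSubclassLinks = 6L,
                 nRestrictions = 3L, nAnnotations = 2L, seed = 17L))
  st1 <- TripleStore()
  st2 <- TripleStore()
  loadRdfXml(st1, g$xml, baseIri = g$ontologyIri, docPath = "mem:same")
  loadRdfXml(st2, g$xml, baseIri = g$ontologyIri, docPath = "mem:same")
  expect_identical(storeSnapshot(st1), storeSnapshot(st2))
  expect_identical(triples(st1), triples(st2))
})
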
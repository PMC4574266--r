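test_that("a fresh store is empty except for the pre-interned vocabulary", {
  st <- TripleStore()
  expect_equal(tripleCount(st), 0L)
  expect_equal(documentCount(st), 0L)
  expect_equal(namespaceCount(st), 4L)
  # standard terms resolvable without loading anything
  id <- lookupIri(st, "http://www.w3.org/2002/07/owl#Class")
  expect_false(is.na(id))
  expect_identical(id, vocabId("owl:Class"))
})

test_that("vocabulary IDs are identical constants across store instances", {
  st1 <- TripleStore()
  st2 <- TripleStore(indexes = "p:sod")
  probes <- c("http://www.w3.org/2002/07/owl#Ontology",
              "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
              "http://www.w3.org/2001/XMLSchema#int",
              "http://www.w3.org/2000/01/rdf-schema#subClassOf")
  expect_identical(lookupIri(st1, probes), lookupIri(st2, probes))
  expect_identical(lookupIri(st1, probes),
                   vapply(probes, vocabId, integer(1), USE.NAMES = FALSE))
})

test_that("IRI interning is idempotent and shares namespace prefixes", {
  st <- TripleStore()
  a <- internIri(st, "http://ex.org/a#B")
  expect_identical(internIri(st, "http://ex.org/a#B"), a)
  cc <- internIri(st, "http://ex.org/a#C")
  expect_false(a == cc)
  expect_identical(getNode(st, a)@ns, getNode(st, cc)@ns)
  expect_error(internIri(st, "no-scheme-here"), class = "owlstore_value_error")
  expect_error(internIri(st, ""), class = "owlstore_value_error")
})

test_that("interning many IRIs over k prefixes grows namespaces by exactly k", {
  st <- TripleStore()
  before <- namespaceCount(st)
  set.seed(42)
  iris <- sprintf("http://example.org/pfx%d#n%d",
                  sample.int(10L, 1000L, replace = TRUE), seq_len(1000L))
  internIri(st, iris)
  expect_equal(namespaceCount(st) - before, 10L)
})

test_that("IRI splitting reconstructs the original exactly", {
  st <- TripleStore()
  cases <- c("http://ex.org/a#B", "http://ex.org/path/leaf",
             "urn:uuid:1234", "http://ex.org/onto#",
             "http://ex.org/x#y#z")
  ids <- internIri(st, cases)
  expect_identical(iriOf(st, ids), cases)
  for (i in seq_along(cases)) {
    node <- getNode(st, ids[i])
    expect_identical(paste0(node@nsIri, node@fragment), cases[i])
  }
})

test_that("literal identity is (datatype, canonical payload, language)", {
  st <- TripleStore()
  xb <- "http://www.w3.org/2001/XMLSchema#boolean"
  xi <- "http://www.w3.org/2001/XMLSchema#int"
  expect_identical(internLiteral(st, "1", xb), internLiteral(st, "true", xb))
  expect_identical(internLiteral(st, "0", xb), internLiteral(st, "false", xb))
  expect_identical(internLiteral(st, "007", xi), internLiteral(st, "7", xi))
  expect_false(internLiteral(st, "dog", language = "en") ==
                 internLiteral(st, "dog", language = "fr"))
  expect_error(internLiteral(st, "abc", xi),
               class = "owlstore_literal_parse_error")
  expect_error(internLiteral(st, "maybe", xb),
               class = "owlstore_literal_parse_error")
  expect_error(internLiteral(st, "5", xi, language = "en"),
               class = "owlstore_value_error")
  # typed payloads round-trip through the node record
  id <- internLiteral(st, "42", xi)
  expect_identical(getNode(st, id)@value, 42)
  expect_identical(getNode(st, internLiteral(st, "true", xb))@value, TRUE)
})

test_that("blank nodes are scoped to their document", {
  st <- TripleStore()
  d1 <- registerDocument(st, "mem:d1")
  d2 <- registerDocument(st, "mem:d2")
  b <- makeBlank(st, d1, "b1")
  expect_identical(makeBlank(st, d1, "b1"), b)
  expect_false(makeBlank(st, d2, "b1") == b)
  expect_error(makeBlank(st, 99L, "x"), class = "owlstore_lookup_error")
  # ordinals count up from zero in first-seen order
  ords <- vapply(c("u", "v", "w"), function(l)
    getNode(st, makeBlank(st, d1, l))@ordinal, integer(1))
  expect_identical(unname(ords), c(1L, 2L, 3L))  # b1 already took ordinal 0
  expect_identical(getNode(st, b)@ordinal, 0L)
})

test_that("triple insertion dedups on (s,p,o,doc) and accepts generalized triples", {
  st <- TripleStore()
  d1 <- registerDocument(st, "mem:d1")
  d2 <- registerDocument(st, "mem:d2")
  a <- internIri(st, "http://ex.org/A")
  b <- internIri(st, "http://ex.org/B")
  p <- internIri(st, "http://ex.org/p")
  addTriple(st, a, p, b, d1)
  addTriple(st, a, p, b, d1)
  expect_equal(tripleCount(st), 1L)
  # same (s,p,o) from another document is a distinct triple
  addTriple(st, a, p, b, d2)
  expect_equal(tripleCount(st), 2L)
  # literal subject is representable (generalized triples)
  lit <- internLiteral(st, "free text")
  addTriple(st, lit, p, a, d1)
  expect_equal(tripleCount(st), 3L)
  expect_equal(nrow(findTriple(st, subj = lit)), 1L)
  expect_error(addTriple(st, 10 * nodeCount(st), p, b, d1),
               class = "owlstore_lookup_error")
  expect_error(addTriple(st, a, p, b, 42L), class = "owlstore_lookup_error")
})

test_that("getObject is the inverse of interning and rejects foreign ids", {
  st <- TripleStore()
  x <- "http://ex.org/vocab#Thing"
  id <- internIri(st, x)
  expect_identical(getNode(st, id)@iri, x)
  expect_identical(getObject(st, id, "node")@iri, x)
  cls <- getNode(st, vocabId("owl:Class"))
  expect_identical(cls@iri, "http://www.w3.org/2002/07/owl#Class")
  d <- registerDocument(st, "mem:doc")
  expect_identical(getDocument(st, d)@path, "mem:doc")
  expect_identical(getNsIri(st, 1L)@iri,
                   "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
  expect_error(getNode(st, nodeCount(st) + 1L),
               class = "owlstore_lookup_error")
  expect_error(getDocument(st, 99L), class = "owlstore_lookup_error")
  expect_error(getNsIri(st, 99L), class = "owlstore_lookup_error")
})

test_that("store construction validates the index configuration", {
  expect_error(TripleStore(indexes = list()), class = "owlstore_config_error")
  expect_error(TripleStore(indexes = "s:pod,s:pod"),
               class = "owlstore_config_error")
  expect_error(TripleStore(indexes = "s:spo"),
               class = "owlstore_config_error")
  expect_error(parseIndexSpec("q:pod"), class = "owlstore_config_error")
  cfg <- parseIndexSpec("o:psd")
  expect_identical(cfg[[1]]$bin, "o")
  expect_identical(cfg[[1]]$sort, c("p", "s", "d"))
})
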
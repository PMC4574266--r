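RDFNS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
OWLNS <- "http://www.w3.org/2002/07/owl#"

wrapRdf <- function(..., base = NULL) {
  paste0('<rdf:RDF xmlns:rdf="', RDFNS, '" xmlns:owl="', OWLNS,
         '" xmlns:ex="http://ex.org/v#"',
         if (!is.null(base)) paste0(' xml:base="', base, '"'), ">\n",
         paste0(..., collapse = "\n"), "\n</rdf:RDF>")
}

test_that("a typed node element emits exactly one rdf:type statement", {
  df <- parseRdfXml(wrapRdf('<owl:Class rdf:about="http://ex.org/A"/>'))
  expect_equal(nrow(df), 1L)
  expect_identical(df$s, "http://ex.org/A")
  expect_identical(df$p, paste0(RDFNS, "type"))
  expect_identical(df$o, paste0(OWLNS, "Class"))
  # rdf:Description emits no type statement
  df2 <- parseRdfXml(wrapRdf('<rdf:Description rdf:about="http://ex.org/A"/>'))
  expect_equal(nrow(df2), 0L)
})

test_that("rdf:parseType='Collection' with 2 members emits 5 list statements", {
  df <- parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:members rdf:parseType="Collection">',
    '    <rdf:Description rdf:about="http://ex.org/B"/>',
    '    <rdf:Description rdf:about="http://ex.org/C"/>',
    '  </ex:members>',
    '</rdf:Description>'))
  expect_equal(nrow(df), 5L)
  expect_equal(sum(df$p == paste0(RDFNS, "first")), 2L)
  expect_equal(sum(df$p == paste0(RDFNS, "rest")), 2L)
  expect_equal(sum(df$o == paste0(RDFNS, "nil")), 1L)
  expect_equal(sum(df$p == "http://ex.org/v#members"), 1L)
  # empty collection points straight at rdf:nil
  df0 <- parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:members rdf:parseType="Collection"/>',
    '</rdf:Description>'))
  expect_equal(nrow(df0), 1L)
  expect_identical(df0$o, paste0(RDFNS, "nil"))
})

test_that("property element forms: resource, nodeID, datatype, lang, nesting", {
  df <- parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:p rdf:resource="http://ex.org/B"/>',
    '  <ex:q rdf:nodeID="nb"/>',
    '  <ex:r rdf:datatype="http://www.w3.org/2001/XMLSchema#int">5</ex:r>',
    '  <ex:s xml:lang="de">hund</ex:s>',
    '  <ex:t><owl:Class rdf:about="http://ex.org/D"/></ex:t>',
    '  <ex:u/>',
    '</rdf:Description>'))
  expect_equal(nrow(df), 7L)  # 6 properties + 1 nested type
  expect_identical(df$o[df$p == "http://ex.org/v#p"], "http://ex.org/B")
  expect_identical(df$oKind[df$p == "http://ex.org/v#q"], "blank")
  expect_identical(df$o[df$p == "http://ex.org/v#q"], "nb")
  expect_identical(df$oDatatype[df$p == "http://ex.org/v#r"],
                   "http://www.w3.org/2001/XMLSchema#int")
  expect_identical(df$oLang[df$p == "http://ex.org/v#s"], "de")
  expect_identical(df$o[df$p == "http://ex.org/v#t"], "http://ex.org/D")
  # empty property element: empty plain literal
  expect_identical(df$o[df$p == "http://ex.org/v#u"], "")
  expect_identical(df$oKind[df$p == "http://ex.org/v#u"], "lit")
})

test_that("parseType Resource and Literal work", {
  df <- parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:p rdf:parseType="Resource"><ex:q rdf:resource="http://ex.org/B"/></ex:p>',
    '  <ex:x rdf:parseType="Literal"><b>bold</b> text</ex:x>',
    '</rdf:Description>'))
  expect_equal(nrow(df), 3L)
  b <- df$o[df$p == "http://ex.org/v#p"]
  expect_identical(df$oKind[df$p == "http://ex.org/v#p"], "blank")
  expect_identical(df$s[df$p == "http://ex.org/v#q"], b)
  lit <- df[df$p == "http://ex.org/v#x", ]
  expect_identical(lit$oDatatype, paste0(RDFNS, "XMLLiteral"))
  expect_match(lit$o, "<b>bold</b>", fixed = TRUE)
})

test_that("xml:base, rdf:ID and relative references resolve", {
  df <- parseRdfXml(wrapRdf(
    '<owl:Class rdf:about="#A"/>',
    '<owl:Class rdf:ID="B"/>',
    '<owl:Class rdf:about="sub/C"/>',
    base = "http://base.org/doc"))
  expect_setequal(df$s, c("http://base.org/doc#A", "http://base.org/doc#B",
                          "http://base.org/sub/C"))
  # the baseIri argument serves when the document declares no xml:base
  df2 <- parseRdfXml(wrapRdf('<owl:Class rdf:about="#A"/>'),
                     baseIri = "http://arg.org/x")
  expect_identical(df2$s, "http://arg.org/x#A")
})

test_that("property attributes expand to statements", {
  df <- parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A" ex:note="hi">',
    '  <ex:p rdf:resource="http://ex.org/B" ex:w="1"/>',
    '</rdf:Description>'))
  expect_equal(nrow(df), 3L)
  expect_identical(df$o[df$p == "http://ex.org/v#note"], "hi")
  # attribute on the property element attaches to the object resource
  expect_identical(df$s[df$p == "http://ex.org/v#w"], "http://ex.org/B")
})

test_that("statements come out in document order with deterministic blanks", {
  xml <- wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:p><rdf:Description><ex:q>x</ex:q></rdf:Description></ex:p>',
    '  <ex:r><rdf:Description><ex:q>y</ex:q></rdf:Description></ex:r>',
    '</rdf:Description>')
  df1 <- parseRdfXml(xml)
  df2 <- parseRdfXml(xml)
  expect_identical(df1, df2)
  blanks <- unique(df1$s[df1$sKind == "blank"])
  expect_identical(blanks, c(".g1", ".g2"))
})

test_that("malformed XML is an xml-stage error", {
  err <- tryCatch(parseRdfXml("<rdf:RDF><unclosed>"),
                  owlstore_load_error = identity)
  expect_s3_class(err, "owlstore_load_error")
  expect_identical(loadErrorStage(err), "xml")
})

test_that("RDF/XML violations are rdf-stage errors", {
  # duplicate rdf:ID
  err <- tryCatch(parseRdfXml(wrapRdf('<owl:Class rdf:ID="X"/>',
                                      '<owl:Class rdf:ID="X"/>',
                                      base = "http://b.org/d")),
                  owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "rdf")
  # relative IRI without a base
  err <- tryCatch(parseRdfXml(wrapRdf('<owl:Class rdf:about="#A"/>')),
                  owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "rdf")
  # unknown parseType
  err <- tryCatch(parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:p rdf:parseType="Bogus"/>',
    '</rdf:Description>')),
    owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "rdf")
  # non-namespaced attribute
  err <- tryCatch(parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A" note="x"/>')),
    owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "rdf")
  # more than one node element inside a property element
  err <- tryCatch(parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:p><owl:Class rdf:about="http://ex.org/B"/>',
    '        <owl:Class rdf:about="http://ex.org/C"/></ex:p>',
    '</rdf:Description>')),
    owlstore_load_error = identity)
  expect_identical(loadErrorStage(err), "rdf")
})

test_that("reification via rdf:ID on a property element emits the 4 extra statements", {
  df <- parseRdfXml(wrapRdf(
    '<rdf:Description rdf:about="http://ex.org/A">',
    '  <ex:p rdf:ID="st1" rdf:resource="http://ex.org/B"/>',
    '</rdf:Description>', base = "http://b.org/d"))
  expect_equal(nrow(df), 5L)
  expect_setequal(
    df$p[df$s == "http://b.org/d#st1"],
    paste0(RDFNS, c("type", "subject", "predicate", "object")))
})
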
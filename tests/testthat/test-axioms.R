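# helpers: load XML text into a fresh store
loadText <- function(xml, base = "http://ex.org/") {
  st <- TripleStore()
  loadRdfXml(st, xml, baseIri = base)
  st
}

EX <- "http://example.org/zoo#"

smallOnto <- function(...) {
  paste0('<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
    xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
    xmlns:owl="http://www.w3.org/2002/07/owl#"
    xmlns:xsd="http://www.w3.org/2001/XMLSchema#"
    xmlns:z="http://example.org/zoo#">
  <owl:Ontology rdf:about="http://example.org/zoo"/>\n',
    paste0(..., collapse = "\n"), "\n</rdf:RDF>")
}

test_that("declarations are collected with kinds, and OP/DP conflict errors", {
  st <- loadText(smallOnto(
    '<owl:Class rdf:about="http://example.org/zoo#A"/>',
    '<owl:ObjectProperty rdf:about="http://example.org/zoo#p"/>',
    '<owl:DatatypeProperty rdf:about="http://example.org/zoo#q"/>',
    '<owl:NamedIndividual rdf:about="http://example.org/zoo#i"/>'))
  decls <- collectDeclarations(st)
  expect_identical(declKind(decls, lookupIri(st, paste0(EX, "A"))), "Class")
  expect_identical(declKind(decls, lookupIri(st, paste0(EX, "p"))),
                   "ObjectProperty")
  expect_identical(declKind(decls, lookupIri(st, paste0(EX, "q"))),
                   "DataProperty")
  expect_null(declKind(decls, lookupIri(st, paste0(EX, "zzz")) %||% 999999L))
  # built-ins are pre-declared
  expect_identical(declKind(decls, vocabId("owl:Thing")), "Class")
  expect_true("AnnotationProperty" %in% declKind(decls, vocabId("rdfs:label")))

  st2 <- loadText(smallOnto(
    '<owl:ObjectProperty rdf:about="http://example.org/zoo#p"/>',
    '<owl:DatatypeProperty rdf:about="http://example.org/zoo#p"/>'))
  expect_error(collectDeclarations(st2),
               class = "owlstore_decl_conflict_error")
})

test_that("punning a class as an individual is allowed", {
  st <- loadText(smallOnto(
    '<owl:Class rdf:about="http://example.org/zoo#A"/>',
    '<owl:NamedIndividual rdf:about="http://example.org/zoo#A"/>'))
  decls <- collectDeclarations(st)
  kinds <- declKind(decls, lookupIri(st, paste0(EX, "A")))
  expect_setequal(kinds, c("Class", "NamedIndividual"))
  expect_equal(sum(vapply(mapAxioms(st), function(a)
    a$kind == "Declaration", logical(1))), 2L)
})

test_that("rdf lists parse in order; malformed lists error with the node", {
  st <- loadText(smallOnto(
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <z:members rdf:parseType="Collection">
         <rdf:Description rdf:about="http://example.org/zoo#X"/>
         <rdf:Description rdf:about="http://example.org/zoo#Y"/>
         <rdf:Description rdf:about="http://example.org/zoo#Z"/>
       </z:members>
     </rdf:Description>'))
  head <- findTriple(st, subj = lookupIri(st, paste0(EX, "A")))$obj[1]
  members <- parseRdfList(st, head)
  expect_identical(iriOf(st, members), paste0(EX, c("X", "Y", "Z")))
  # rdf:nil is the empty list
  expect_identical(parseRdfList(st, vocabId("rdf:nil")), integer(0))
  # branching: a cell with two rdf:rest out-edges
  d <- registerDocument(st, "mem:extra")
  cell <- makeBlank(st, d, "cell")
  addTriple(st, cell, vocabId("rdf:first"),
            internIri(st, paste0(EX, "X")), d)
  addTriple(st, cell, vocabId("rdf:rest"), vocabId("rdf:nil"), d)
  addTriple(st, cell, vocabId("rdf:rest"), cell, d)
  expect_error(parseRdfList(st, cell), class = "owlstore_mapping_error")
})

test_that("class expressions parse: booleans, enumeration, restrictions", {
  st <- loadText(smallOnto(
    '<owl:Class rdf:about="http://example.org/zoo#A"/>',
    '<owl:Class rdf:about="http://example.org/zoo#B"/>',
    '<owl:ObjectProperty rdf:about="http://example.org/zoo#p"/>',
    '<owl:NamedIndividual rdf:about="http://example.org/zoo#i"/>',
    '<owl:NamedIndividual rdf:about="http://example.org/zoo#j"/>',
    '<rdf:Description rdf:about="http://example.org/zoo#B">
       <owl:equivalentClass>
         <owl:Class>
           <owl:unionOf rdf:parseType="Collection">
             <owl:Class rdf:about="http://example.org/zoo#A"/>
             <owl:Restriction>
               <owl:onProperty rdf:resource="http://example.org/zoo#p"/>
               <owl:allValuesFrom rdf:resource="http://example.org/zoo#A"/>
             </owl:Restriction>
           </owl:unionOf>
         </owl:Class>
       </owl:equivalentClass>
     </rdf:Description>'))
  ax <- mapAxioms(st)
  strs <- axiomStrings(ax, st)
  expect_true(any(grepl(
    "EquivalentClasses\\(<.*#B> ObjectUnionOf\\(<.*#A> ObjectAllValuesFrom\\(<.*#p> <.*#A>\\)\\)\\)",
    strs)))
})

test_that("parseClassExpression reports each malformation distinctly", {
  base <- c(
    '<owl:Class rdf:about="http://example.org/zoo#A"/>',
    '<owl:ObjectProperty rdf:about="http://example.org/zoo#p"/>')
  # restriction without onProperty
  st <- loadText(smallOnto(base,
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <rdfs:subClassOf>
         <owl:Restriction>
           <owl:someValuesFrom rdf:resource="http://example.org/zoo#A"/>
         </owl:Restriction>
       </rdfs:subClassOf>
     </rdf:Description>'))
  expect_error(mapAxioms(st), regexp = "owl:onProperty",
               class = "owlstore_mapping_error")
  # restriction with two filler keys
  st <- loadText(smallOnto(base,
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <rdfs:subClassOf>
         <owl:Restriction>
           <owl:onProperty rdf:resource="http://example.org/zoo#p"/>
           <owl:someValuesFrom rdf:resource="http://example.org/zoo#A"/>
           <owl:allValuesFrom rdf:resource="http://example.org/zoo#A"/>
         </owl:Restriction>
       </rdfs:subClassOf>
     </rdf:Description>'))
  expect_error(mapAxioms(st), regexp = "filler",
               class = "owlstore_mapping_error")
  # negative cardinality
  st <- loadText(smallOnto(base,
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <rdfs:subClassOf>
         <owl:Restriction>
           <owl:onProperty rdf:resource="http://example.org/zoo#p"/>
           <owl:minCardinality rdf:datatype="http://www.w3.org/2001/XMLSchema#int"
             >-2</owl:minCardinality>
         </owl:Restriction>
       </rdfs:subClassOf>
     </rdf:Description>'))
  expect_error(mapAxioms(st), regexp = "non-negative",
               class = "owlstore_mapping_error")
  # undeclared named superclass
  st <- loadText(smallOnto(base,
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <rdfs:subClassOf rdf:resource="http://example.org/zoo#Ghost"/>
     </rdf:Description>'))
  expect_error(mapAxioms(st), regexp = "undeclared class",
               class = "owlstore_mapping_error")
  # extra triples hanging off an expression node
  st <- loadText(smallOnto(base,
    '<owl:AnnotationProperty rdf:about="http://example.org/zoo#note"/>',
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <rdfs:subClassOf>
         <owl:Restriction>
           <owl:onProperty rdf:resource="http://example.org/zoo#p"/>
           <owl:someValuesFrom rdf:resource="http://example.org/zoo#A"/>
           <z:note>stray</z:note>
         </owl:Restriction>
       </rdfs:subClassOf>
     </rdf:Description>'))
  expect_error(mapAxioms(st), regexp = "extra triples",
               class = "owlstore_mapping_error")
})

test_that("the full supported axiom surface maps and serializes", {
  st <- loadText(richOntologyXml())
  ax <- mapAxioms(st)
  strs <- sort(axiomStrings(ax, st))
  expect_true(sprintf("Ontology(<%s>)", "http://example.org/zoo") %in% strs)
  expect_true(any(grepl("^DisjointClasses\\(<.*Cat> <.*Dog>\\)$", strs)))
  expect_true(any(grepl("^FunctionalObjectProperty\\(<.*hasOwner>\\)$", strs)))
  expect_true(any(grepl("^ObjectPropertyDomain", strs)))
  expect_true(any(grepl("^DataPropertyRange\\(<.*age> <.*int>\\)$", strs)))
  expect_true(any(grepl("^ClassAssertion\\(<.*Dog> <.*rex>\\)$", strs)))
  expect_true(any(grepl("^ObjectPropertyAssertion\\(<.*hasOwner> <.*rex> <.*alice>\\)$", strs)))
  # "007"^^xsd:int canonicalizes to 7
  expect_true(any(grepl(
    "^DataPropertyAssertion\\(<.*age> <.*rex> \"7\"\\^\\^<.*int>\\)$", strs)))
  expect_true(any(grepl("^AnnotationAssertion\\(<.*label> <.*rex> \"Rex\"@en\\)$", strs)))
  expect_true(any(grepl(
    "^EquivalentClasses\\(<.*Pet> ObjectIntersectionOf\\(<.*Animal> ObjectSomeValuesFrom\\(<.*hasOwner> <.*Animal>\\)\\)\\)$",
    strs)))
  expect_true(any(grepl("ObjectMaxCardinality\\(2 <.*hasOwner>\\)", strs)))

  # the serialized document is deterministic and contains every axiom
  txt1 <- serializeFunctional(ax, st)
  txt2 <- serializeFunctional(mapAxioms(st), st)
  expect_identical(txt1, txt2)
  expect_match(txt1, "Prefix(zoo:=<http://example.org/zoo#>)", fixed = TRUE)
  expect_match(txt1, "SubClassOf(zoo:Dog zoo:Animal)", fixed = TRUE)
})

test_that("strict error taxonomy: undeclared predicate and misspelled term", {
  st <- loadText(smallOnto(
    '<owl:Class rdf:about="http://example.org/zoo#A"/>',
    '<owl:Class rdf:about="http://example.org/zoo#B"/>',
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <z:partOf rdf:resource="http://example.org/zoo#B"/>
     </rdf:Description>'))
  err <- tryCatch(mapAxioms(st), owlstore_mapping_error = identity)
  expect_s3_class(err, "owlstore_undeclared_predicate_error")
  expect_match(conditionMessage(err), "partOf")

  st <- loadText(smallOnto(
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <rdf:type rdf:resource="http://www.w3.org/2002/07/owl#Classs"/>
     </rdf:Description>'))
  err <- tryCatch(mapAxioms(st), owlstore_mapping_error = identity)
  expect_s3_class(err, "owlstore_misspelled_term_error")
  expect_match(conditionMessage(err), "Classs")
})

test_that("unsupported constructs are detected, not mis-mapped", {
  st <- loadText(smallOnto(
    '<owl:ObjectProperty rdf:about="http://example.org/zoo#p"/>',
    '<owl:ObjectProperty rdf:about="http://example.org/zoo#q"/>',
    '<rdf:Description rdf:about="http://example.org/zoo#p">
       <owl:inverseOf rdf:resource="http://example.org/zoo#q"/>
     </rdf:Description>'))
  expect_error(mapAxioms(st),
               class = "owlstore_unsupported_construct_error")
})

test_that("strictness is monotone in declarations", {
  body <- '<rdf:Description rdf:about="http://example.org/zoo#A">
             <z:rel rdf:resource="http://example.org/zoo#B"/>
           </rdf:Description>'
  decls <- c('<owl:Class rdf:about="http://example.org/zoo#A"/>',
             '<owl:Class rdf:about="http://example.org/zoo#B"/>',
             '<owl:ObjectProperty rdf:about="http://example.org/zoo#rel"/>')
  # with all declarations: valid
  expect_silent(ax <- mapAxioms(loadText(smallOnto(decls, body))))
  # removing the property declaration always triggers the error
  expect_error(mapAxioms(loadText(smallOnto(decls[1:2], body))),
               class = "owlstore_undeclared_predicate_error")
  # adding an unrelated declaration never invalidates the document
  extra <- '<owl:Class rdf:about="http://example.org/zoo#Unrelated"/>'
  expect_silent(mapAxioms(loadText(smallOnto(decls, extra, body))))
})

test_that("abort atomicity: errors come from conditions, never partial output", {
  st <- loadText(smallOnto(
    '<owl:Class rdf:about="http://example.org/zoo#A"/>',
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <z:undeclared rdf:resource="http://example.org/zoo#A"/>
     </rdf:Description>'))
  got <- tryCatch(mapAxioms(st), owlstore_mapping_error = function(e) "aborted")
  expect_identical(got, "aborted")
})

test_that("reified owl:Axiom annotations attach to their axiom", {
  st <- loadText(smallOnto(
    '<owl:Class rdf:about="http://example.org/zoo#A"/>',
    '<owl:Class rdf:about="http://example.org/zoo#B"/>',
    '<rdf:Description rdf:about="http://example.org/zoo#A">
       <rdfs:subClassOf rdf:resource="http://example.org/zoo#B"/>
     </rdf:Description>',
    '<owl:Axiom>
       <owl:annotatedSource rdf:resource="http://example.org/zoo#A"/>
       <owl:annotatedProperty rdf:resource="http://www.w3.org/2000/01/rdf-schema#subClassOf"/>
       <owl:annotatedTarget rdf:resource="http://example.org/zoo#B"/>
       <rdfs:comment>why A is a B</rdfs:comment>
     </owl:Axiom>'))
  ax <- mapAxioms(st)
  strs <- axiomStrings(ax, st)
  hit <- grep("^SubClassOf\\(Annotation\\(", strs, value = TRUE)
  expect_length(hit, 1L)
  expect_match(hit, "why A is a B", fixed = TRUE)
})

test_that("scoping by document translates only that document", {
  g1 <- generateOntologyDocument(ontologySpec(nClasses = 3L,
                                              nSubclassLinks = 2L, seed = 31L),
                                 ontologyIri = "http://example.org/s1")
  g2 <- generateOntologyDocument(ontologySpec(nClasses = 4L,
                                              nSubclassLinks = 1L, seed = 32L),
                                 ontologyIri = "http://example.org/s2")
  st <- TripleStore()
  d1 <- loadRdfXml(st, g1$xml, baseIri = g1$ontologyIri, docPath = "mem:1")
  d2 <- loadRdfXml(st, g2$xml, baseIri = g2$ontologyIri, docPath = "mem:2")
  expect_setequal(axiomStrings(mapAxioms(st, doc = d1), st), g1$axioms)
  expect_setequal(axiomStrings(mapAxioms(st, doc = d2), st), g2$axioms)
  both <- axiomStrings(mapAxioms(st), st)
  expect_setequal(both, c(g1$axioms, g2$axioms))
})

test_that("an empty ontology maps to just its header and serializes", {
  st <- loadText(smallOnto(""))
  ax <- mapAxioms(st)
  expect_length(ax, 1L)
  expect_identical(ax[[1]]$kind, "Ontology")
  txt <- serializeFunctional(ax, st)
  expect_match(txt, "Ontology(exampleorg:zoo\n)", fixed = TRUE)
})
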
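test_that("an empty graph serializes to just the prefix block", {
  g <- ontology_graph()
  txt <- write_turtle(g)
  lines <- strsplit(txt, "\n")[[1]]
  expect_true(all(grepl("^@prefix ", lines)))
  expect_true(graph_equal(read_turtle(txt), g))
})

test_that("serialization is deterministic, byte for byte", {
  g <- build_core_schema()
  expect_identical(write_turtle(g), write_turtle(g))
  g2 <- random_fixture_graph(5)
  expect_identical(write_turtle(g2), write_turtle(g2))
  # and stable across a round-trip
  expect_identical(write_turtle(g), write_turtle(read_turtle(write_turtle(g))))
})

test_that("write -> read is the identity on toolkit-produced graphs", {
  expect_true(graph_equal(read_turtle(write_turtle(build_core_schema())),
                          build_core_schema()))
  card <- read_card(fixture_card_path("hiv-social-network.yaml"))
  g <- to_instance_graph(card)
  expect_true(graph_equal(read_turtle(write_turtle(g)), g))
  for (seed in 1:40) {
    g <- random_fixture_graph(seed)
    expect_true(graph_equal(read_turtle(write_turtle(g)), g),
                label = paste("roundtrip seed", seed))
  }
})

test_that("metrics are invariant under serialization round-trip", {
  for (seed in c(1, 12, 30)) {
    g <- random_fixture_graph(seed)
    expect_equal(ontology_stats(read_turtle(write_turtle(g))),
                 ontology_stats(g))
  }
})

test_that("OWL characteristics map directly to axiom kinds on read", {
  txt <- paste(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix ex: <http://example.org/> .",
    "ex:p a owl:ObjectProperty , owl:TransitiveObjectProperty .",
    "ex:q a owl:ObjectProperty ;",
    "    owl:inverseOf ex:p .",
    sep = "\n")
  g <- read_turtle(txt)
  expect_true(any(g$axioms$kind == "transitive-property" &
                    g$axioms$subject == "http://example.org/p"))
  expect_true(any(g$axioms$kind == "inverse-of"))
})

test_that("literals with datatypes, language tags and escapes survive", {
  g <- ontology_graph()
  g <- add_term(g, "mcri:x", "individual")
  g <- add_term(g, "skos:note", "annotation-property")
  g <- add_term(g, "mcro:val", "data-property")
  for (lit in tricky_literals)
    g <- add_axiom(g, "annotation-assertion", "mcri:x", predicate = "skos:note",
                   object = lit, literal = TRUE)
  g <- add_axiom(g, "annotation-assertion", "mcri:x", predicate = "skos:note",
                 object = "hello", literal = TRUE, lang = "en")
  g <- add_axiom(g, "data-property-assertion", "mcri:x", predicate = "mcro:val",
                 object = "42", literal = TRUE, datatype = "xsd:integer")
  g2 <- read_turtle(write_turtle(g))
  expect_true(graph_equal(g2, g))
  ann <- g2$axioms[g2$axioms$kind == "annotation-assertion", ]
  expect_true(all(tricky_literals %in% ann$object))
  expect_equal(ann$lang[ann$object == "hello"], "en")
})

test_that("syntax errors report a line number", {
  bad <- "@prefix ex: <http://example.org/> .\nex:a ex:b %%% .\n"
  expect_error(read_turtle(bad), "line 2")
  expect_error(read_turtle("ex:a ex:b ex:c ."), "unknown prefix")
})

test_that("blank-node constructs are recorded as unsupported, not dropped silently", {
  txt <- paste(
    "@prefix ex: <http://example.org/> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "ex:A rdfs:subClassOf [ ex:onProperty ex:p ] .",
    "ex:A rdfs:subClassOf ex:B .",
    sep = "\n")
  expect_warning(g <- read_turtle(txt), "unsupported")
  expect_true(length(g$unsupported) >= 1)
  # the parseable statement is still there
  expect_true(any(g$axioms$kind == "subclass-of" &
                    g$axioms$object == "http://example.org/B"))
})

test_that("unsupported OWL characteristics are flagged on read", {
  txt <- paste(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix ex: <http://example.org/> .",
    "ex:p a owl:ObjectProperty , owl:FunctionalProperty .",
    sep = "\n")
  expect_warning(g <- read_turtle(txt), "unsupported")
  expect_match(g$unsupported, "FunctionalProperty", all = FALSE)
})

test_that("OWL/XML output is well-formed and element counts match axioms", {
  # empty graph: minimal valid ontology document
  doc <- xml2::read_xml(write_owl_xml(ontology_graph()))
  expect_equal(xml2::xml_name(doc), "Ontology")
  # core schema: parses, and one element per axiom of each kind
  g <- build_core_schema()
  doc <- xml2::read_xml(write_owl_xml(g))
  ns <- xml2::xml_ns(doc)
  count_el <- function(name)
    length(xml2::xml_find_all(doc, paste0(".//d1:", name), ns))
  expect_equal(count_el("Declaration"), nrow(g$terms))
  expect_equal(count_el("SubClassOf"), sum(g$axioms$kind == "subclass-of"))
  expect_equal(count_el("EquivalentClasses"),
               sum(g$axioms$kind == "equivalent-class"))
  expect_equal(count_el("TransitiveObjectProperty"), 1L)
  expect_equal(count_el("InverseObjectProperties"), 1L)
  # a single type assertion yields exactly one ClassAssertion element
  h <- ontology_graph()
  h <- add_term(h, "mcro:A", "class")
  h <- add_term(h, "mcri:x", "individual")
  h <- add_axiom(h, "type-assertion", "mcri:x", object = "mcro:A")
  doc <- xml2::read_xml(write_owl_xml(h))
  expect_length(xml2::xml_find_all(doc, ".//d1:ClassAssertion",
                                   xml2::xml_ns(doc)), 1L)
})
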
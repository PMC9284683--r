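schema <- build_core_schema()

has_axiom <- function(g, kind, subject, object = NA, predicate = NA) {
  p <- g$prefixes
  ax <- g$axioms[g$axioms$kind == kind, , drop = FALSE]
  s <- expand_curie(subject, p)
  o <- if (!is.na(object)) expand_curie(object, p) else NA
  hit <- ax$subject == s
  if (!is.na(object)) hit <- hit & ax$object == o
  if (kind %in% c("equivalent-class", "disjoint-with") && !is.na(object))
    hit <- hit | (ax$subject == o & ax$object == s)  # stored normalized
  if (!is.na(predicate)) hit <- hit & ax$predicate == expand_curie(predicate, p)
  any(hit)
}

test_that("alignment axioms use the printed external identifiers", {
  # equivalences
  expect_true(has_axiom(schema, "equivalent-class", "mcro:ReferenceInformation",
                        "obo:IAO_0000320"))
  expect_true(has_axiom(schema, "equivalent-class", "mcro:Graphic",
                        "obo:IAO_0000038"))
  # is-about links
  about <- list(c("mcro:DatasetInformation", "obo:IAO_0000100"),
                c("mcro:ModelArchitecture", "obo:IAO_0000064"),
                c("mcro:FormatInformation", "obo:IAO_0000098"),
                c("mcro:VersionInformation", "obo:IAO_0000129"),
                c("mcro:LicenseInformation", "swo:SWO_0000002"))
  for (pair in about)
    expect_true(has_axiom(schema, "object-property-assertion", pair[1],
                          pair[2], predicate = "obo:IAO_0000136"))
  # citation link
  expect_true(has_axiom(schema, "object-property-assertion",
                        "mcro:CitationInformation", "obo:IAO_0000301",
                        predicate = "obo:BFO_0000051"))
  # every externally printed IRI present with its full PURL
  expect_true(all(table2_iris() %in% schema$terms$iri))
})

test_that("partonomy characteristics and report alignment are declared", {
  expect_true(has_axiom(schema, "transitive-property", "obo:BFO_0000051"))
  expect_true(has_axiom(schema, "inverse-of", "obo:BFO_0000051",
                        "obo:BFO_0000050"))
  expect_true(has_axiom(schema, "subclass-of", "mcro:ModelCardReport",
                        "obo:IAO_0000088"))
  for (k in section_kinds(main_only = TRUE)) {
    expect_true(has_axiom(schema, "subclass-of", paste0("mcro:", k),
                          "obo:IAO_0000314"))
    expect_true(has_axiom(schema, "object-property-assertion",
                          "mcro:ModelCardReport", paste0("mcro:", k),
                          predicate = "obo:BFO_0000051"))
  }
  expect_true(has_axiom(schema, "subclass-of", "mcro:GraphicCollection",
                        "skos:Collection"))
  expect_true(has_axiom(schema, "disjoint-with", "obo:IAO_0000064",
                        "swo:SWO_0000001"))
})

test_that("trade-off class carries the alternative label Caveats", {
  ax <- schema$axioms
  hit <- ax$kind == "annotation-assertion" &
    ax$subject == expand_curie("mcro:TradeOff") &
    ax$predicate == expand_curie("obo:IAO_0000118") &
    ax$object == "Caveats"
  expect_equal(sum(hit), 1L)
})

test_that("schema construction is deterministic and self-consistent", {
  expect_true(graph_equal(schema, build_core_schema()))
  expect_equal(nrow(check_consistency(schema)), 0L)
})

test_that("the quantitative-analysis to graphic-collection edge is configurable", {
  g_about <- build_core_schema(graphic_collection_link = "is-about")
  expect_true(has_axiom(g_about, "object-property-assertion",
                        "mcro:QuantitativeAnalysis", "mcro:GraphicCollection",
                        predicate = "obo:IAO_0000136"))
  expect_false(has_axiom(g_about, "object-property-assertion",
                         "mcro:QuantitativeAnalysis", "mcro:GraphicCollection",
                         predicate = "obo:BFO_0000051"))
  expect_true(has_axiom(schema, "object-property-assertion",
                        "mcro:QuantitativeAnalysis", "mcro:GraphicCollection",
                        predicate = "obo:BFO_0000051"))
})

test_that("metrics match an independent statement enumeration", {
  expect_equal(unclass(ontology_stats(ontology_graph()))[1:4],
               list(n_classes = 0L, n_object_properties = 0L,
                    n_data_properties = 0L, n_logical_axioms = 0L))
  s <- ontology_stats(schema)
  o <- oracle_stats_from_turtle(write_turtle(schema))
  expect_equal(s$n_classes, o$n_classes)
  expect_equal(s$n_object_properties, o$n_object_properties)
  expect_equal(s$n_data_properties, o$n_data_properties)
  expect_equal(s$n_logical_axioms, o$n_logical_axioms)
})

test_that("metrics error on unclosed graphs, naming the dangling IRI", {
  g <- ontology_graph()
  g <- add_term(g, "mcro:A", "class")
  g <- add_term(g, "mcro:B", "class")
  g <- add_axiom(g, "subclass-of", "mcro:A", object = "mcro:B")
  g$terms <- g$terms[g$terms$iri != expand_curie("mcro:B"), ]
  expect_error(ontology_stats(g), "not closed.*mcro#B")
})
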
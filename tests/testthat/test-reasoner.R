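hp <- "http://purl.obolibrary.org/obo/BFO_0000051"
po <- "http://purl.obolibrary.org/obo/BFO_0000050"

op_edges <- function(g, prop) {
  ax <- g$axioms
  ax <- ax[ax$kind == "object-property-assertion" & ax$predicate == prop, ]
  data.frame(from = ax$subject, to = ax$object, stringsAsFactors = FALSE)
}

axiom_in <- function(m, ax) {
  key <- function(a) paste(a$kind, a$subject, a$predicate, a$object, a$object_type)
  key(ax) %in% key(m$axioms)
}

test_that("partonomy inferences go beyond the first-degree connection", {
  card <- model_card("demo", "Demo", list(
    card_section("Considerations",
                 children = list(card_section("TradeOff")))))
  g <- to_instance_graph(card)
  m <- materialize(g)
  inds <- g$terms$iri[g$terms$category == "individual"]
  card_i <- inds[grepl("instance/demo$", inds)]
  cons_i <- inds[grepl("considerations", inds)]
  trade_i <- inds[grepl("tradeoff", inds)]
  has <- function(p, a, b) {
    e <- op_edges(m, p)
    any(e$from == a & e$to == b)
  }
  expect_true(has(hp, card_i, trade_i))   # transitive
  expect_true(has(po, trade_i, cons_i))   # inverse
  expect_true(has(po, trade_i, card_i))   # both
  expect_true(has(po, cons_i, card_i))
  # and they are flagged as inferred while the input is untouched
  expect_true(all(axiom_in(m, g$axioms)))
})

test_that("materializing an empty graph returns an empty graph", {
  g <- ontology_graph()
  expect_true(graph_equal(materialize(g), g))
})

test_that("closure of random partonomy DAGs equals breadth-first reachability", {
  for (seed in 1:40) {
    g <- random_partonomy_graph(seed, max_individuals = 8)
    m <- materialize(g)
    want <- oracle_reachability(asserted_edges(g))
    got <- op_edges(m, hp)
    expect_equal(edge_set(got), edge_set(want), info = paste("seed", seed))
    # part-of is the exact transpose of the has-part closure
    inv <- op_edges(m, po)
    expect_equal(edge_set(inv),
                 edge_set(data.frame(from = got$to, to = got$from)),
                 info = paste("seed", seed))
  }
})

test_that("materialization is idempotent and monotone", {
  for (seed in c(2, 11, 23)) {
    g <- random_partonomy_graph(seed)
    m <- materialize(g)
    expect_true(graph_equal(materialize(m), m))
    expect_true(all(axiom_in(m, g$axioms)))   # G subset of materialize(G)
  }
})

test_that("subclass, equivalence and type rules propagate", {
  g <- ontology_graph()
  for (cl in c("mcro:A", "mcro:B", "mcro:C", "mcro:D"))
    g <- add_term(g, cl, "class")
  g <- add_term(g, "mcri:x", "individual")
  g <- add_axiom(g, "subclass-of", "mcro:A", object = "mcro:B")
  g <- add_axiom(g, "subclass-of", "mcro:B", object = "mcro:C")
  g <- add_axiom(g, "equivalent-class", "mcro:C", object = "mcro:D")
  g <- add_axiom(g, "type-assertion", "mcri:x", object = "mcro:A")
  m <- materialize(g)
  sc <- m$axioms[m$axioms$kind == "subclass-of", ]
  expect_true(any(sc$subject == expand_curie("mcro:A") &
                    sc$object == expand_curie("mcro:C")))
  expect_true(any(sc$subject == expand_curie("mcro:D") &
                    sc$object == expand_curie("mcro:C"))) # equivalence both ways
  ty <- m$axioms[m$axioms$kind == "type-assertion" &
                   m$axioms$subject == expand_curie("mcri:x"), ]
  expect_setequal(ty$object, expand_curie(c("mcro:A", "mcro:B", "mcro:C",
                                            "mcro:D")))
})

test_that("an individual typed software and algorithm is exactly one inconsistency", {
  g <- build_core_schema()
  g <- add_term(g, "mcri:de-acme-variant", "individual",
                "differential evolution (acme-variant)")
  g <- add_axiom(g, "type-assertion", "mcri:de-acme-variant",
                 object = "swo:SWO_0000001")
  g <- add_axiom(g, "type-assertion", "mcri:de-acme-variant",
                 object = "obo:IAO_0000064")
  inc <- check_consistency(g)
  expect_equal(nrow(inc), 1L)
  expect_equal(inc$individual, expand_curie("mcri:de-acme-variant"))
  expect_setequal(c(inc$class_a, inc$class_b),
                  expand_curie(c("swo:SWO_0000001", "obo:IAO_0000064")))
  expect_equal(nrow(check_consistency(build_core_schema())), 0L)
})

test_that("disjointness declared on superclasses is enforced on subclasses", {
  g <- ontology_graph()
  for (cl in c("mcro:Software", "mcro:Algorithm", "mcro:Script"))
    g <- add_term(g, cl, "class")
  g <- add_term(g, "mcri:x", "individual")
  g <- add_axiom(g, "disjoint-with", "mcro:Software", object = "mcro:Algorithm")
  g <- add_axiom(g, "subclass-of", "mcro:Script", object = "mcro:Software")
  g <- add_axiom(g, "type-assertion", "mcri:x", object = "mcro:Script")
  g <- add_axiom(g, "type-assertion", "mcri:x", object = "mcro:Algorithm")
  inc <- check_consistency(g)
  expect_equal(nrow(inc), 1L)
  expect_true("inferred" %in% c(inc$provenance_a, inc$provenance_b))
})

test_that("violation detection matches exhaustive enumeration on random graphs", {
  for (seed in 1:25) {
    set.seed(seed)
    g <- ontology_graph()
    ncls <- sample(3:6, 1)
    cls <- sprintf("mcro:C%d", seq_len(ncls))
    for (cl in cls) g <- add_term(g, cl, "class")
    for (i in seq_len(ncls - 1))
      if (runif(1) < 0.5)
        g <- add_axiom(g, "subclass-of", cls[i + 1], object = cls[i])
    pairs <- utils::combn(ncls, 2)
    for (k in sample(ncol(pairs), min(2, ncol(pairs))))
      g <- add_axiom(g, "disjoint-with", cls[pairs[1, k]],
                     object = cls[pairs[2, k]])
    for (i in seq_len(sample(2:8, 1))) {
      x <- sprintf("mcri:i%d", i)
      g <- add_term(g, x, "individual")
      for (cl in sample(cls, sample(1:3, 1)))
        g <- add_axiom(g, "type-assertion", x, object = cl)
    }
    inc <- check_consistency(g)
    got <- sort(paste(inc$individual, inc$class_a, inc$class_b))
    expect_equal(got, oracle_inconsistencies(g), info = paste("seed", seed))
  }
})
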
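# Shared fixtures (built in code) and independent oracles. The oracles use
# different algorithms from the implementation: breadth-first search instead
# of matrix closure, naive saturation instead of the semi-naive engine, and
# a primitive statement enumerator instead of the Turtle reader.

## ---- random partonomy instance graphs -----------------------------------

# a random DAG of individuals wired with has-part, over a minimal schema
# carrying the partonomy characteristics (transitive has-part, inverse part-of)
random_partonomy_graph <- function(seed, max_individuals = 10) {
  set.seed(seed)
  n <- sample(2:max_individuals, 1)
  g <- ontology_graph()
  g <- add_term(g, "mcro:Node", "class", "node")
  g <- add_term(g, "obo:BFO_0000051", "object-property", "has part")
  g <- add_term(g, "obo:BFO_0000050", "object-property", "part of")
  g <- add_axiom(g, "transitive-property", "obo:BFO_0000051")
  g <- add_axiom(g, "inverse-of", "obo:BFO_0000051",
                 object = "obo:BFO_0000050")
  ind <- sprintf("mcri:n%02d", seq_len(n))
  for (x in ind) {
    g <- add_term(g, x, "individual")
    g <- add_axiom(g, "type-assertion", x, object = "mcro:Node")
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < 0.35)
        g <- add_axiom(g, "object-property-assertion", ind[i],
                       predicate = "obo:BFO_0000051", object = ind[j])
    }
  }
  g
}

# asserted has-part edges of a graph, as a two-column data frame
asserted_edges <- function(g, prop = "http://purl.obolibrary.org/obo/BFO_0000051") {
  ax <- g$axioms
  ax <- ax[ax$kind == "object-property-assertion" & !ax$inferred &
             ax$predicate == prop, , drop = FALSE]
  data.frame(from = ax$subject, to = ax$object, stringsAsFactors = FALSE)
}

# brute-force all-pairs reachability by breadth-first search (paths >= 1 edge)
oracle_reachability <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  out <- data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  for (s in nodes) {
    seen <- character()
    queue <- adj[[s]]
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!v %in% seen) {
        seen <- c(seen, v)
        queue <- c(queue, adj[[v]])
      }
    }
    if (length(seen))
      out <- rbind(out, data.frame(from = s, to = seen,
                                   stringsAsFactors = FALSE))
  }
  out
}

edge_set <- function(df) sort(paste(df$from, df$to))

## ---- consistency oracle ---------------------------------------------------

# exhaustive enumeration: for every individual and every disjoint pair, test
# membership using type sets computed by naive saturation over the subclass
# and equivalence axiom lists
oracle_inconsistencies <- function(g) {
  ax <- g$axioms[!g$axioms$inferred, , drop = FALSE]
  sup <- function(cls) {
    seen <- cls
    repeat {
      more <- unique(c(
        ax$object[ax$kind == "subclass-of" & ax$subject %in% seen],
        ax$object[ax$kind == "equivalent-class" & ax$subject %in% seen],
        ax$subject[ax$kind == "equivalent-class" & ax$object %in% seen]))
      new <- setdiff(more, seen)
      if (!length(new)) return(seen)
      seen <- c(seen, new)
    }
  }
  ty <- ax[ax$kind == "type-assertion", , drop = FALSE]
  dj <- ax[ax$kind == "disjoint-with", , drop = FALSE]
  hits <- character()
  for (ind in unique(ty$subject)) {
    types <- unique(unlist(lapply(ty$object[ty$subject == ind], sup)))
    for (j in seq_len(nrow(dj))) {
      if (dj$subject[j] %in% types && dj$object[j] %in% types) {
        pair <- sort(c(dj$subject[j], dj$object[j]))
        hits <- c(hits, paste(ind, pair[1], pair[2]))
      }
    }
  }
  sort(unique(hits))
}

## ---- statement enumeration oracle for stats -------------------------------

# independent one-off enumerator over the serialized Turtle text: expands the
# grouped blocks back into single statements and counts by kind. Only safe
# for graphs whose literals do not contain the writer's separator sequences
# (the core schema qualifies).
oracle_stats_from_turtle <- function(txt) {
  blocks <- strsplit(txt, "\n\n", fixed = TRUE)[[1]]
  blocks <- blocks[!startsWith(blocks, "@prefix")]
  blocks <- blocks[!grepl(" a owl:Ontology", blocks)]
  n_class <- n_op <- n_dp <- n_logical <- 0L
  ann_props <- c("rdfs:label", "obo:IAO_0000118", "skos:note",
                 "dcterms:description", "dcterms:date", "dcterms:source",
                 "dcterms:title", "skos:altLabel")
  for (b in blocks) {
    b <- sub(" \\.\\s*$", "", b)
    b <- gsub("\n    ", " ", b)
    first_sp <- regexpr(" ", b)
    groups <- strsplit(substring(b, first_sp + 1L), " ; ", fixed = TRUE)[[1]]
    for (grp in groups) {
      sp <- regexpr(" ", grp)
      pred <- substring(grp, 1L, sp - 1L)
      objs <- strsplit(substring(grp, sp + 1L), " , ", fixed = TRUE)[[1]]
      if (pred == "a") {
        for (o in objs) {
          if (o == "owl:Class") n_class <- n_class + 1L
          else if (o == "owl:ObjectProperty") n_op <- n_op + 1L
          else if (o == "owl:DatatypeProperty") n_dp <- n_dp + 1L
          else if (o == "owl:TransitiveObjectProperty")
            n_logical <- n_logical + 1L
          else if (o %in% c("owl:AnnotationProperty", "owl:NamedIndividual")) {
            # declarations: not logical
          } else n_logical <- n_logical + 1L      # type assertion
        }
      } else if (pred %in% ann_props || startsWith(pred, "rdfs:label")) {
        # annotations: not logical
      } else {
        n_logical <- n_logical + length(objs)
      }
    }
  }
  list(n_classes = n_class, n_object_properties = n_op,
       n_data_properties = n_dp, n_logical_axioms = n_logical)
}

## ---- random serialization fixtures ----------------------------------------

tricky_literals <- c("plain text", "with \"quotes\"", "line\nbreak",
                     "tab\tseparated", "backslash \\ here",
                     "comma , semicolon ; dot .", "accent é")

# a random mixed schema/instance graph exercising every serializable axiom
# kind and literal shape
random_fixture_graph <- function(seed) {
  set.seed(seed)
  g <- ontology_graph()
  ncls <- sample(2:5, 1)
  cls <- sprintf("mcro:Class%d", seq_len(ncls))
  for (i in seq_along(cls))
    g <- add_term(g, cls[i], "class",
                  if (stats::runif(1) < 0.7) paste("class", i) else NA_character_)
  g <- add_term(g, "mcro:hasPiece", "object-property", "has piece")
  g <- add_term(g, "mcro:pieceOf", "object-property", "piece of")
  g <- add_term(g, "mcro:weight", "data-property", "weight")
  g <- add_term(g, "skos:note", "annotation-property", "note")
  g <- add_axiom(g, "transitive-property", "mcro:hasPiece")
  g <- add_axiom(g, "inverse-of", "mcro:hasPiece", object = "mcro:pieceOf")
  g <- add_axiom(g, "domain", "mcro:hasPiece", object = cls[1])
  g <- add_axiom(g, "range", "mcro:hasPiece", object = cls[ncls])
  for (i in seq_len(ncls - 1))
    if (stats::runif(1) < 0.8)
      g <- add_axiom(g, "subclass-of", cls[i + 1], object = cls[i])
  if (ncls >= 3 && stats::runif(1) < 0.5)
    g <- add_axiom(g, "equivalent-class", cls[2], object = cls[3])
  if (stats::runif(1) < 0.5)
    g <- add_axiom(g, "disjoint-with", cls[1], object = cls[ncls])
  nind <- sample(1:6, 1)
  ind <- sprintf("mcri:item%d", seq_len(nind))
  for (x in ind) {
    g <- add_term(g, x, "individual")
    g <- add_axiom(g, "type-assertion", x,
                   object = cls[sample(ncls, 1)])
    if (stats::runif(1) < 0.6)
      g <- add_axiom(g, "data-property-assertion", x,
                     predicate = "mcro:weight",
                     object = as.character(sample(100, 1)), literal = TRUE,
                     datatype = "xsd:integer")
    if (stats::runif(1) < 0.6) {
      lang <- if (stats::runif(1) < 0.3) "en" else NA_character_
      g <- add_axiom(g, "annotation-assertion", x, predicate = "skos:note",
                     object = sample(tricky_literals, 1), literal = TRUE,
                     lang = lang)
    }
  }
  if (nind >= 2) {
    for (k in seq_len(nind - 1))
      if (stats::runif(1) < 0.5)
        g <- add_axiom(g, "object-property-assertion", ind[k],
                       predicate = "mcro:hasPiece", object = ind[k + 1])
  }
  g
}

## ---- synthetic software-ontology-like source for extraction ---------------

# a class hierarchy reminiscent of a large software ontology: the eight
# alignment target terms plus parents and unrelated siblings
synthetic_swo_like <- function() {
  g <- ontology_graph()
  add_cls <- function(g, curie, label, parent = NULL) {
    g <- add_term(g, curie, "class", label)
    if (!is.null(parent))
      g <- add_axiom(g, "subclass-of", curie, object = parent)
    g
  }
  g <- add_cls(g, "obo:BFO_0000001", "entity")
  g <- add_cls(g, "obo:IAO_0000030", "information content entity",
               "obo:BFO_0000001")
  g <- add_cls(g, "obo:IAO_0000100", "data set", "obo:IAO_0000030")
  g <- add_cls(g, "obo:IAO_0000064", "algorithm", "obo:IAO_0000030")
  g <- add_cls(g, "obo:IAO_0000098", "data format specification",
               "obo:IAO_0000030")
  g <- add_cls(g, "obo:IAO_0000129", "version number", "obo:IAO_0000030")
  g <- add_cls(g, "obo:IAO_0000310", "document", "obo:IAO_0000030")
  g <- add_cls(g, "obo:IAO_0000314", "document part", "obo:IAO_0000030")
  g <- add_cls(g, "obo:IAO_0000320", "reference section", "obo:IAO_0000314")
  g <- add_cls(g, "obo:IAO_0000038", "graph", "obo:IAO_0000030")
  g <- add_cls(g, "obo:IAO_0000301", "citation", "obo:IAO_0000030")
  g <- add_cls(g, "swo:SWO_0000001", "software", "obo:IAO_0000030")
  g <- add_cls(g, "swo:SWO_0000002", "license", "obo:IAO_0000030")
  # unrelated siblings that must NOT survive extraction
  g <- add_cls(g, "swo:SWO_9000001", "compiler", "swo:SWO_0000001")
  g <- add_cls(g, "swo:SWO_9000002", "interpreter", "swo:SWO_0000001")
  g <- add_cls(g, "swo:SWO_9000003", "text editor", "swo:SWO_0000001")
  g <- add_term(g, "obo:BFO_0000051", "object-property", "has part")
  g <- add_axiom(g, "transitive-property", "obo:BFO_0000051")
  g <- add_axiom(g, "object-property-assertion", "obo:IAO_0000310",
                 predicate = "obo:BFO_0000051", object = "obo:IAO_0000314")
  g
}

table2_iris <- function() {
  c("http://purl.obolibrary.org/obo/IAO_0000100",
    "http://purl.obolibrary.org/obo/IAO_0000064",
    "http://purl.obolibrary.org/obo/IAO_0000098",
    "http://purl.obolibrary.org/obo/IAO_0000129",
    "http://purl.obolibrary.org/obo/IAO_0000320",
    "http://purl.obolibrary.org/obo/IAO_0000038",
    "http://purl.obolibrary.org/obo/IAO_0000301",
    "http://www.ebi.ac.uk/swo/SWO_0000002",
    "http://purl.obolibrary.org/obo/BFO_0000051",
    "http://purl.obolibrary.org/obo/IAO_0000136")
}

# independent tree walk over a card (different traversal from count_sections)
oracle_section_count <- function(card) {
  n <- 0L
  stack <- card$sections
  while (length(stack)) {
    s <- stack[[1]]; stack <- stack[-1]
    n <- n + 1L
    stack <- c(stack, s$children)
  }
  n
}

fixture_card_path <- function(name) {
  p <- system.file("extdata", "cards", name, package = "mcrotools")
  if (!nzchar(p))
    p <- file.path("..", "..", "inst", "extdata", "cards", name)
  p
}
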
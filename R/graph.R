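# Core container: an ontology graph is a term table, an axiom table and a
# prefix map. Both schema and instance data live in the same structure.

#' Term categories recognized in an ontology graph
#' @export
TERM_CATEGORIES <- c("class", "object-property", "data-property",
                     "annotation-property", "individual")

#' Axiom kinds recognized in an ontology graph
#'
#' `declaration` exists at the serialization boundary only: declarations are
#' carried by the term table (each term's `category`), never stored as axiom
#' rows.
#' @export
AXIOM_KINDS <- c("subclass-of", "equivalent-class", "disjoint-with",
                 "transitive-property", "inverse-of", "domain", "range",
                 "type-assertion", "object-property-assertion",
                 "data-property-assertion", "annotation-assertion",
                 "declaration")

# axiom kinds that count as logical (ontology-editor metric): everything except
# declarations and pure annotations
LOGICAL_KINDS <- setdiff(AXIOM_KINDS, c("annotation-assertion", "declaration"))

empty_terms <- function() {
  data.frame(iri = character(), label = character(), category = character(),
             stringsAsFactors = FALSE)
}

empty_axioms <- function() {
  data.frame(kind = character(), subject = character(), predicate = character(),
             object = character(), object_type = character(),
             datatype = character(), lang = character(), inferred = logical(),
             stringsAsFactors = FALSE)
}

#' Create an empty ontology graph
#'
#' An `ontology_graph` holds a set of terms (IRI, label, category), a set of
#' axioms, and a prefix table mapping prefix strings to namespace IRIs. Terms
#' play the role of OWL declarations; axioms carry the logical and annotation
#' statements. Axioms have set semantics: adding an identical axiom twice
#' stores it once.
#'
#' @param prefixes named character vector mapping prefixes to namespace IRIs;
#'   defaults to the standard namespaces used by the model card schema.
#' @return an object of class `ontology_graph`
#' @export
ontology_graph <- function(prefixes = default_prefixes()) {
  g <- list(terms = empty_terms(), axioms = empty_axioms(),
            prefixes = prefixes, ontology_iri = NA_character_,
            unsupported = character())
  class(g) <- "ontology_graph"
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  s <- ontology_stats(x, check = FALSE)
  cat(sprintf(
    "<ontology_graph> %d terms, %d axioms (%d classes, %d obj props, %d data props, %d logical axioms)\n",
    nrow(x$terms), nrow(x$axioms), s$n_classes, s$n_object_properties,
    s$n_data_properties, s$n_logical_axioms))
  invisible(x)
}

#' Add a term to an ontology graph
#'
#' A term's category is immutable: re-adding an existing IRI with a different
#' category is an error; re-adding with the same category is a no-op (a
#' non-missing label fills in a missing one).
#'
#' @param g ontology_graph
#' @param iri absolute IRI or CURIE (expanded against the graph's prefixes)
#' @param category one of [TERM_CATEGORIES]
#' @param label optional human-readable label
#' @return the updated graph
#' @export
add_term <- function(g, iri, category, label = NA_character_) {
  stopifnot(inherits(g, "ontology_graph"), length(iri) == 1L)
  if (!category %in% TERM_CATEGORIES)
    stop("unknown term category: ", category, call. = FALSE)
  iri <- expand_curie(iri, g$prefixes)
  i <- match(iri, g$terms$iri)
  if (!is.na(i)) {
    if (g$terms$category[i] != category)
      stop(sprintf("term <%s> already declared as %s; categories are immutable",
                   iri, g$terms$category[i]), call. = FALSE)
    if (is.na(g$terms$label[i]) && !is.na(label)) g$terms$label[i] <- label
    return(g)
  }
  g$terms <- rbind(g$terms, data.frame(iri = iri, label = label,
                                       category = category,
                                       stringsAsFactors = FALSE))
  g
}

#' Look up whether a term exists
#' @param g ontology_graph
#' @param iri IRI or CURIE
#' @return logical
#' @export
has_term <- function(g, iri) {
  expand_curie(iri, g$prefixes) %in% g$terms$iri
}

term_category <- function(g, iri) {
  i <- match(iri, g$terms$iri)
  if (is.na(i)) NA_character_ else g$terms$category[i]
}

#' Compact view of the graph's term set
#'
#' @param g ontology_graph
#' @return data frame with columns `iri`, `curie`, `label`, `category`
#' @export
graph_terms <- function(g) {
  t <- g$terms
  t$curie <- vapply(t$iri, compact_iri, "", prefixes = g$prefixes)
  t[order(t$iri), c("iri", "curie", "label", "category")]
}

axiom_key <- function(ax) {
  paste(ax$kind, ax$subject, ax$predicate, ax$object, ax$object_type,
        ax$datatype, ax$lang, sep = "\r")
}

# category requirements per axiom kind; NA = unconstrained
.kind_rules <- list(
  "subclass-of"              = list(subject = "class", object = "class"),
  "equivalent-class"         = list(subject = "class", object = "class"),
  "disjoint-with"            = list(subject = "class", object = "class"),
  "transitive-property"      = list(subject = "object-property", object = NA),
  "inverse-of"               = list(subject = "object-property",
                                    object = "object-property"),
  "domain"                   = list(subject = c("object-property",
                                                "data-property"),
                                    object = "class"),
  "range"                    = list(subject = c("object-property",
                                                "data-property"),
                                    object = NA),
  "type-assertion"           = list(subject = "individual", object = "class"),
  "object-property-assertion"= list(subject = NA, object = NA),
  "data-property-assertion"  = list(subject = NA, object = NA),
  "annotation-assertion"     = list(subject = NA, object = NA)
)

#' Add an axiom to an ontology graph
#'
#' Axioms are validated against their kind: e.g. `subclass-of` requires two
#' class terms, `transitive-property` an object-property subject, and logical
#' axioms never carry literal subjects. Every referenced term must already be
#' in the graph (the graph stays closed by construction). Symmetric kinds
#' (`equivalent-class`, `disjoint-with`) are normalized so the
#' lexicographically smaller IRI is the subject, giving deterministic
#' counting.
#'
#' @param g ontology_graph
#' @param kind one of [AXIOM_KINDS] except `declaration`
#' @param subject subject term IRI/CURIE
#' @param predicate predicate term IRI/CURIE, for assertion kinds
#' @param object object term IRI/CURIE, or literal text when `literal = TRUE`
#' @param literal is `object` a literal?
#' @param datatype,lang optional literal datatype IRI / language tag
#' @param inferred marks axioms added by the reasoner
#' @return the updated graph
#' @export
add_axiom <- function(g, kind, subject, predicate = NA_character_,
                      object = NA_character_, literal = FALSE,
                      datatype = NA_character_, lang = NA_character_,
                      inferred = FALSE) {
  stopifnot(inherits(g, "ontology_graph"))
  if (!kind %in% AXIOM_KINDS || kind == "declaration")
    stop("unknown or unsupported axiom kind: ", kind, call. = FALSE)
  subject <- expand_curie(subject, g$prefixes)
  if (!is.na(predicate)) predicate <- expand_curie(predicate, g$prefixes)
  if (!literal && !is.na(object)) object <- expand_curie(object, g$prefixes)
  if (!is.na(datatype)) {
    datatype <- expand_curie(datatype, g$prefixes)
    # xsd:string is the literal default; normalize so serialization (which
    # omits it) round-trips
    if (datatype == "http://www.w3.org/2001/XMLSchema#string")
      datatype <- NA_character_
  }

  if (literal && kind %in% LOGICAL_KINDS &&
      !kind %in% c("data-property-assertion", "range"))
    stop("axiom kind ", kind, " cannot carry a literal object", call. = FALSE)
  if (kind == "data-property-assertion" && !literal)
    stop("data-property-assertion requires a literal object", call. = FALSE)

  check_cat <- function(iri, want, role) {
    if (length(want) == 1L && is.na(want)) return(invisible())
    got <- term_category(g, iri)
    if (is.na(got))
      stop(sprintf("axiom references undeclared term <%s>", iri), call. = FALSE)
    if (!got %in% want)
      stop(sprintf("%s axiom requires %s %s, got %s <%s>",
                   kind, paste(want, collapse = "/"), role, got, iri),
           call. = FALSE)
    invisible()
  }
  rules <- .kind_rules[[kind]]
  check_cat(subject, rules$subject, "subject")
  if (!literal && !is.na(object)) {
    check_cat(object, rules$object, "object")
    if (!has_term(g, object))
      stop(sprintf("axiom references undeclared term <%s>", object),
           call. = FALSE)
  }
  if (!has_term(g, subject))
    stop(sprintf("axiom references undeclared term <%s>", subject),
         call. = FALSE)
  if (!is.na(predicate) && !has_term(g, predicate))
    stop(sprintf("axiom references undeclared term <%s>", predicate),
         call. = FALSE)
  if (kind == "object-property-assertion") {
    if (is.na(predicate) || term_category(g, predicate) != "object-property")
      stop("object-property-assertion requires an object-property predicate",
           call. = FALSE)
  }
  if (kind == "data-property-assertion") {
    if (is.na(predicate) || term_category(g, predicate) != "data-property")
      stop("data-property-assertion requires a data-property predicate",
           call. = FALSE)
  }
  if (kind == "annotation-assertion") {
    if (is.na(predicate) ||
        term_category(g, predicate) != "annotation-property")
      stop("annotation-assertion requires an annotation-property predicate",
           call. = FALSE)
  }

  # normalize symmetric kinds for deterministic, direction-free storage
  if (kind %in% c("equivalent-class", "disjoint-with") && object < subject) {
    tmp <- subject; subject <- object; object <- tmp
  }

  row <- data.frame(kind = kind, subject = subject, predicate = predicate,
                    object = object,
                    object_type = if (literal) "literal" else "iri",
                    datatype = datatype, lang = lang, inferred = inferred,
                    stringsAsFactors = FALSE)
  if (axiom_key(row) %in% axiom_key(g$axioms)) return(g)
  g$axioms <- rbind(g$axioms, row)
  g
}

#' Check that a graph is closed
#'
#' Closed means every IRI appearing in an axiom has a term record. Violations
#' raise an error naming the first dangling IRI.
#'
#' @param g ontology_graph
#' @return the graph, invisibly
#' @export
assert_closed <- function(g) {
  ax <- g$axioms
  iris <- c(ax$subject, ax$predicate[!is.na(ax$predicate)],
            ax$object[!is.na(ax$object) & ax$object_type == "iri"])
  dangling <- setdiff(unique(iris), g$terms$iri)
  if (length(dangling))
    stop("graph is not closed: dangling IRI <", dangling[[1]], ">",
         call. = FALSE)
  invisible(g)
}

#' Test two graphs for equality
#'
#' Equality is plain set equality of terms and axioms plus equal prefix
#' tables: no blank nodes exist, so no isomorphism search is needed.
#'
#' @param a,b ontology_graph objects
#' @param ignore_inferred drop the inferred flag before comparing
#' @return logical
#' @export
graph_equal <- function(a, b, ignore_inferred = FALSE) {
  norm_terms <- function(g) {
    t <- g$terms[order(g$terms$iri), c("iri", "label", "category")]
    rownames(t) <- NULL
    t
  }
  norm_ax <- function(g) {
    ax <- g$axioms
    if (ignore_inferred) ax$inferred <- NULL
    ax <- ax[order(axiom_key(g$axioms)), , drop = FALSE]
    rownames(ax) <- NULL
    ax
  }
  norm_prefix <- function(g) g$prefixes[order(names(g$prefixes))]
  identical(norm_terms(a), norm_terms(b)) &&
    identical(norm_ax(a), norm_ax(b)) &&
    identical(norm_prefix(a), norm_prefix(b))
}

#' Merge two ontology graphs
#'
#' Union of term sets, axiom sets and prefix tables. Conflicting term
#' categories or prefix bindings are errors.
#'
#' @param a,b ontology_graph objects
#' @return merged ontology_graph
#' @export
merge_graphs <- function(a, b) {
  common <- intersect(names(a$prefixes), names(b$prefixes))
  bad <- common[a$prefixes[common] != b$prefixes[common]]
  if (length(bad))
    stop("conflicting prefix binding for '", bad[[1]], "'", call. = FALSE)
  g <- a
  g$prefixes <- c(a$prefixes, b$prefixes[setdiff(names(b$prefixes), common)])
  for (i in seq_len(nrow(b$terms)))
    g <- add_term(g, b$terms$iri[i], b$terms$category[i], b$terms$label[i])
  new <- !(axiom_key(b$axioms) %in% axiom_key(g$axioms))
  g$axioms <- rbind(g$axioms, b$axioms[new, , drop = FALSE])
  rownames(g$axioms) <- NULL
  g
}

# subset of axioms by kind, convenience
axioms_of_kind <- function(g, kinds) {
  g$axioms[g$axioms$kind %in% kinds, , drop = FALSE]
}
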
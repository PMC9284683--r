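# Minimal triple-pattern matching over (optionally materialized) graphs:
# the smallest facility that demonstrates inference-aware search over
# published model cards.

#' Match a triple pattern against a graph
#'
#' Matches assertion-level axioms (type assertions and object/data/annotation
#' property assertions) against a single `(subject, predicate, object)`
#' pattern. `NULL` (or `"?"`) is a wildcard. Type assertions match with
#' predicate `rdf:type`. With `infer = TRUE` the pattern is evaluated against
#' [materialize()] of the graph, so e.g. parts beyond the first degree are
#' found through the transitive partonomy.
#'
#' @param g ontology_graph
#' @param subject,predicate,object pattern positions: an IRI/CURIE, `"?"` or
#'   `NULL` for a wildcard; `object` may also match literal values exactly
#' @param infer evaluate against the materialized graph
#' @return data frame of bindings with columns `subject`, `predicate`,
#'   `object`, `object_type`, `kind`, `inferred`; one row per matching axiom
#' @export
match_triples <- function(g, subject = NULL, predicate = NULL, object = NULL,
                          infer = FALSE) {
  assert_closed(g)
  norm <- function(x, literal_ok = FALSE) {
    if (is.null(x) || (length(x) == 1L && x == "?")) return(NULL)
    expanded <- expand_curie(x, g$prefixes)
    if (!literal_ok && !has_term(g, expanded))
      stop("unresolvable term in pattern: ", x, call. = FALSE)
    expanded
  }
  s <- norm(subject)
  p <- if (!is.null(predicate) &&
           (identical(predicate, "a") ||
            identical(expand_curie(predicate, g$prefixes), RDF_TYPE)))
    RDF_TYPE else norm(predicate)
  o <- if (is.null(object) || (length(object) == 1L && object == "?")) NULL
       else object

  if (infer) g <- materialize(g)
  ax <- g$axioms[g$axioms$kind %in%
                   c("type-assertion", "object-property-assertion",
                     "data-property-assertion", "annotation-assertion"), ,
                 drop = FALSE]
  pred_col <- ifelse(ax$kind == "type-assertion", RDF_TYPE, ax$predicate)
  keep <- rep(TRUE, nrow(ax))
  if (!is.null(s)) keep <- keep & ax$subject == s
  if (!is.null(p)) keep <- keep & pred_col == p
  if (!is.null(o)) {
    o_iri <- tryCatch(expand_curie(o, g$prefixes), error = function(e) o)
    keep <- keep & ((ax$object_type == "iri" & ax$object == o_iri) |
                      (ax$object_type == "literal" & ax$object == o))
  }
  out <- data.frame(subject = ax$subject[keep],
                    predicate = pred_col[keep],
                    object = ax$object[keep],
                    object_type = ax$object_type[keep],
                    kind = ax$kind[keep],
                    inferred = ax$inferred[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
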
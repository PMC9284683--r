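# Seed-based subset extraction: given seed terms, keep the seeds, their
# transitive superclass closure, every property used by retained axioms, and
# exactly those axioms whose terms are all retained. This is the minimal
# upward-closure variant sufficient for importing a filtered slice of a
# large source ontology.

#' Read a seed-term list file
#'
#' One IRI or CURIE per line, UTF-8; `#` starts a comment; blank lines are
#' ignored.
#'
#' @param path file path
#' @param prefixes prefix table used to expand CURIEs
#' @return character vector of absolute IRIs
#' @export
read_seed_file <- function(path, prefixes = default_prefixes()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vapply(lines, expand_curie, "", prefixes = prefixes, USE.NAMES = FALSE)
}

#' Extract a seed-based subset of an ontology
#'
#' The subset contains (1) every seed term, (2) the transitive superclass
#' closure of every seed (following subclass-of and equivalent-class axioms
#' upward), (3) every property term used by a retained axiom, and (4) exactly
#' those axioms whose subject, predicate and object terms are all retained.
#' The result is closed; extraction is monotone in the seed set and a
#' fixpoint (re-extracting with the same seeds is the identity).
#'
#' @param g source ontology_graph
#' @param seeds character vector of IRIs/CURIEs; all must exist in `g`
#' @return ontology_graph
#' @export
extract_subset <- function(g, seeds) {
  assert_closed(g)
  seeds <- vapply(seeds, expand_curie, "", prefixes = g$prefixes,
                  USE.NAMES = FALSE)
  missing <- setdiff(seeds, g$terms$iri)
  if (length(missing))
    stop("unknown seed IRI(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  ax <- g$axioms
  # upward edges: subclass-of plus both directions of equivalent-class
  eq <- ax[ax$kind == "equivalent-class", , drop = FALSE]
  up <- rbind(ax[ax$kind == "subclass-of", c("subject", "object")],
              eq[, c("subject", "object")],
              data.frame(subject = eq$object, object = eq$subject,
                         stringsAsFactors = FALSE))

  keep <- unique(seeds)
  inv <- ax[ax$kind == "inverse-of", , drop = FALSE]
  repeat {
    n0 <- length(keep)
    # superclass closure
    keep <- union(keep, up$object[up$subject %in% keep])
    # a property is used as soon as an axiom between retained terms names it
    used <- ax$subject %in% keep &
      (is.na(ax$object) | ax$object_type == "literal" | ax$object %in% keep)
    keep <- union(keep, stats::na.omit(ax$predicate[used]))
    # retained properties carry their characteristics: pull inverse partners
    keep <- union(keep, inv$object[inv$subject %in% keep])
    keep <- union(keep, inv$subject[inv$object %in% keep])
    if (length(keep) == n0) break
  }

  out <- ontology_graph(prefixes = g$prefixes)
  out$ontology_iri <- g$ontology_iri
  t <- g$terms[g$terms$iri %in% keep, , drop = FALSE]
  rownames(t) <- NULL
  out$terms <- t
  out$axioms <- ax[axiom_retained(ax, keep), , drop = FALSE]
  rownames(out$axioms) <- NULL
  assert_closed(out)
}

# which axioms reference only retained terms
axiom_retained <- function(ax, keep) {
  s_ok <- ax$subject %in% keep
  p_ok <- is.na(ax$predicate) | ax$predicate %in% keep
  o_ok <- is.na(ax$object) | ax$object_type == "literal" |
    ax$object %in% keep
  s_ok & p_ok & o_ok
}
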
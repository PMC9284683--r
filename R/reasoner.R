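# Forward-chaining materialization for the rule fragment the schema
# exercises, replacing an external OWL reasoner:
#   R1 transitivity:  p transitive, <a p b>, <b p c>  =>  <a p c>
#   R2 inverse:       p inverseOf q, <a p b>          =>  <b q a>  (both ways)
#   R3 subclass:      A < B, B < C                    =>  A < C
#   R4 types:         x : A, A < B                    =>  x : B
#   R5 equivalence:   A = B                           =>  A < B, B < A
# plus pairwise disjointness checking over the materialized types.
# Property chains, functionality and cardinality are deliberately out of
# scope; such constructs are flagged on read, never silently dropped.

#' Materialize the deductive closure of a graph
#'
#' Computes the least fixpoint of the transitivity, inverse, subclass, type
#' inheritance and equivalence rules (semi-naive evaluation: each round only
#' joins facts derived in the previous round against the full set). The input
#' graph is contained in the output; derived axioms carry `inferred = TRUE`.
#' Termination is guaranteed: the rules are monotone over the finite set of
#' terms.
#'
#' @param g a closed ontology_graph
#' @return ontology_graph extended with inferred axioms
#' @export
materialize <- function(g) {
  assert_closed(g)
  ax <- g$axioms

  ## ---- class-level closure: R5 then R3 -------------------------------
  eq <- ax[ax$kind == "equivalent-class", , drop = FALSE]
  sc <- unique(rbind(
    ax[ax$kind == "subclass-of", c("subject", "object")],
    data.frame(subject = eq$subject, object = eq$object,
               stringsAsFactors = FALSE),
    data.frame(subject = eq$object, object = eq$subject,
               stringsAsFactors = FALSE)))
  sc_closed <- transitive_pairs(sc)

  ## ---- R4: type inheritance over the closed subclass relation --------
  ty <- ax[ax$kind == "type-assertion", c("subject", "object")]
  if (nrow(ty) && nrow(sc_closed)) {
    new_ty <- merge(ty, sc_closed, by.x = "object", by.y = "subject")
    ty <- unique(rbind(ty, data.frame(subject = new_ty$subject,
                                      object = new_ty$object.y,
                                      stringsAsFactors = FALSE)))
  }

  ## ---- R1 + R2: object-property assertions ---------------------------
  trans_props <- ax$subject[ax$kind == "transitive-property"]
  inv <- ax[ax$kind == "inverse-of", c("subject", "object")]
  op <- ax[ax$kind == "object-property-assertion" & ax$object_type == "iri",
           c("subject", "predicate", "object")]
  op <- unique(op)

  inv_map <- c(stats::setNames(inv$object, inv$subject),
               stats::setNames(inv$subject, inv$object))

  apply_inverse <- function(edges) {
    if (!nrow(edges)) return(edges)
    flip <- edges[edges$predicate %in% names(inv_map), , drop = FALSE]
    if (!nrow(flip)) return(edges)
    unique(rbind(edges, data.frame(subject = flip$object,
                                   predicate = unname(inv_map[flip$predicate]),
                                   object = flip$subject,
                                   stringsAsFactors = FALSE)))
  }
  apply_trans <- function(edges) {
    out <- edges
    for (p in unique(trans_props)) {
      e <- out[out$predicate == p, c("subject", "object")]
      if (!nrow(e)) next
      closed <- transitive_pairs(e)
      out <- unique(rbind(out, data.frame(subject = closed$subject,
                                          predicate = p,
                                          object = closed$object,
                                          stringsAsFactors = FALSE)))
    }
    out
  }
  # alternate the two rules to fixpoint (an inverse of a transitive property
  # becomes transitively closed through the flip of the closed edges)
  repeat {
    n0 <- nrow(op)
    op <- apply_trans(apply_inverse(op))
    if (nrow(op) == n0) break
  }

  ## ---- assemble output ------------------------------------------------
  out <- g
  add_new <- function(out, kind, df, predicate = NA_character_) {
    if (!nrow(df)) return(out)
    for (i in seq_len(nrow(df))) {
      p <- if ("predicate" %in% names(df)) df$predicate[i] else predicate
      out <- add_axiom(out, kind, df$subject[i], predicate = p,
                       object = df$object[i], inferred = TRUE)
    }
    out
  }
  out <- add_new(out, "subclass-of", sc_closed)
  out <- add_new(out, "type-assertion", ty)
  out <- add_new(out, "object-property-assertion", op)
  out
}

# transitive closure of a 2-column edge frame (subject, object); returns the
# closed pair set (no self loops added unless present via a cycle)
transitive_pairs <- function(edges) {
  names(edges) <- c("subject", "object")
  edges <- unique(edges)
  nodes <- unique(c(edges$subject, edges$object))
  n <- length(nodes)
  if (!n) return(edges)
  m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  m[cbind(edges$subject, edges$object)] <- TRUE
  for (k in seq_len(n))        # Floyd-Warshall reachability
    m <- m | (m[, k] %o% m[k, ])
  idx <- which(m, arr.ind = TRUE)
  data.frame(subject = nodes[idx[, 1]], object = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Check a graph for disjointness violations
#'
#' Materializes the graph internally, then reports one inconsistency per
#' individual and unordered pair of disjoint classes the individual is typed
#' by. Because type inheritance runs first, disjointness declared on
#' superclasses is enforced on all subclasses.
#'
#' @param g ontology_graph
#' @return data frame of class `inconsistency_set` with columns `individual`,
#'   `class_a`, `class_b`, `provenance_a`, `provenance_b` (asserted/inferred);
#'   zero rows means consistent
#' @export
check_consistency <- function(g) {
  m <- materialize(g)
  ty <- m$axioms[m$axioms$kind == "type-assertion", , drop = FALSE]
  dj <- m$axioms[m$axioms$kind == "disjoint-with", , drop = FALSE]
  out <- data.frame(individual = character(), class_a = character(),
                    class_b = character(), provenance_a = character(),
                    provenance_b = character(), stringsAsFactors = FALSE)
  if (nrow(dj) && nrow(ty)) {
    for (ind in unique(ty$subject)) {
      tt <- ty[ty$subject == ind, , drop = FALSE]
      for (j in seq_len(nrow(dj))) {
        a <- dj$subject[j]; b <- dj$object[j]
        ia <- match(a, tt$object); ib <- match(b, tt$object)
        if (!is.na(ia) && !is.na(ib)) {
          cls <- sort(c(a, b))
          prov <- ifelse(tt$inferred[c(ia, ib)][order(c(a, b))],
                         "inferred", "asserted")
          out <- rbind(out, data.frame(
            individual = ind, class_a = cls[1], class_b = cls[2],
            provenance_a = prov[1], provenance_b = prov[2],
            stringsAsFactors = FALSE))
        }
      }
    }
    out <- unique(out)
    out <- out[order(out$individual, out$class_a, out$class_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("inconsistency_set", "data.frame")
  out
}

#' @export
print.inconsistency_set <- function(x, ...) {
  if (!nrow(x)) {
    cat("consistent: no disjointness violations\n")
  } else {
    cat(nrow(x), "inconsistenc", if (nrow(x) == 1) "y" else "ies", ":\n",
        sep = "")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  <%s> typed by disjoint classes <%s> (%s) and <%s> (%s)\n",
                  x$individual[i], x$class_a[i], x$provenance_a[i],
                  x$class_b[i], x$provenance_b[i]))
  }
  invisible(x)
}
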
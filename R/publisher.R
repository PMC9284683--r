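# Publish a model card as an instance graph over the core schema: one
# individual per card and per section, typed by the section classes, wired
# with has-part assertions, annotated with note/description/date/source.

# small deterministic string hash (FNV-1a, 32-bit, rendered as 6 hex chars);
# used to mint stable individual identifiers from section paths
stable_hash <- function(x) {
  # 32-bit modular multiply in two 16-bit halves to stay inside exact
  # double-precision integer range
  mulmod32 <- function(h, m) {
    h1 <- h %/% 65536
    h0 <- h %% 65536
    (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- mulmod32(h, 16777619)
  }
  sprintf("%06x", h %% 16777216)
}

slugify <- function(x) {
  s <- tolower(gsub("[^A-Za-z0-9]+", "-", x))
  gsub("^-|-$", "", s)
}

#' Publish a model card as an ontology instance graph
#'
#' Returns the schema plus instance triples: one individual typed
#' `mcro:ModelCardReport` for the card, one individual per section typed by
#' its kind class, parent-child structure as *has part*
#' (`obo:BFO_0000051`) assertions, and the card title, section headings,
#' bodies and annotations as annotation assertions (`dcterms:title`,
#' `skos:note`, `dcterms:description`, `dcterms:date`, `dcterms:source`).
#' Body text is attached through the description property; note/date/source
#' only when supplied.
#'
#' Individual identifiers are deterministic: the card individual is the
#' card-id slug in the instance namespace, each section individual appends
#' its kind slug and a short stable hash of its position path, so
#' re-publication of the same card reproduces the same graph.
#'
#' @param card model_card
#' @param schema ontology_graph containing all section kind classes
#'   (typically [build_core_schema()])
#' @return ontology_graph (schema plus instance data)
#' @export
to_instance_graph <- function(card, schema = build_core_schema()) {
  validate_card(card)
  g <- schema
  # resolve each kind's class IRI and fail early on vocabulary gaps
  kind_iri <- function(kind) {
    iri <- expand_curie(paste0("mcro:", kind), g$prefixes)
    if (!has_term(g, iri))
      stop("section kind '", kind, "' is missing from the schema",
           call. = FALSE)
    iri
  }
  for (k in unique(c("ModelCardReport", all_kinds(card)))) kind_iri(k)

  ann_props <- c(note = "skos:note", description = "dcterms:description",
                 date = "dcterms:date", source = "dcterms:source")

  card_iri <- expand_curie(paste0("mcri:", slugify(card$card_id)), g$prefixes)
  g <- add_term(g, card_iri, "individual", card$title)
  g <- add_axiom(g, "type-assertion", card_iri, object = kind_iri("ModelCardReport"))
  g <- add_axiom(g, "annotation-assertion", card_iri,
                 predicate = "dcterms:title", object = card$title,
                 literal = TRUE)

  add_section <- function(g, s, parent_iri, path) {
    iri <- expand_curie(sprintf("mcri:%s-%s-%s", slugify(card$card_id),
                                slugify(s$kind), stable_hash(path)),
                        g$prefixes)
    g <- add_term(g, iri, "individual",
                  if (nzchar(s$heading)) s$heading else s$kind)
    g <- add_axiom(g, "type-assertion", iri, object = kind_iri(s$kind))
    g <- add_axiom(g, "object-property-assertion", parent_iri,
                   predicate = "obo:BFO_0000051", object = iri)
    if (nzchar(s$body))
      g <- add_axiom(g, "annotation-assertion", iri,
                     predicate = "dcterms:description", object = s$body,
                     literal = TRUE)
    for (key in names(s$annotations)) {
      if (key == "description" && nzchar(s$body)) {
        # body already occupies description; keep the extra text as a note
        g <- add_axiom(g, "annotation-assertion", iri,
                       predicate = "skos:note",
                       object = s$annotations[[key]], literal = TRUE)
      } else {
        g <- add_axiom(g, "annotation-assertion", iri,
                       predicate = ann_props[[key]],
                       object = s$annotations[[key]], literal = TRUE)
      }
    }
    for (i in seq_along(s$children))
      g <- add_section(g, s$children[[i]], iri, paste0(path, ".", i))
    g
  }
  for (i in seq_along(card$sections))
    g <- add_section(g, card$sections[[i]], card_iri, as.character(i))
  assert_closed(g)
}

all_kinds <- function(card) {
  walk <- function(s) c(s$kind, unlist(lapply(s$children, walk)))
  unlist(lapply(card$sections, walk)) %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
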
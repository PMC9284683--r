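# Document model for model card reports and its on-disk authoring format.
# Cards are authored as YAML: one card per file, explicit kind tags per
# section, nested children. This stands in for hand-entry in an ontology
# editor; the publisher turns a card into an instance graph.

ANNOTATION_KEYS <- c("note", "description", "date", "source")

#' Construct a model card
#'
#' @param card_id stable slug (non-empty; letters, digits, `-`, `_`)
#' @param title card title
#' @param sections list of [card_section()] objects
#' @return object of class `model_card`
#' @export
model_card <- function(card_id, title, sections = list()) {
  if (!is.character(card_id) || length(card_id) != 1L || !nzchar(card_id))
    stop("card_id must be a non-empty string", call. = FALSE)
  if (!grepl("^[A-Za-z0-9][A-Za-z0-9_-]*$", card_id))
    stop("card_id must be a slug (letters, digits, '-', '_')", call. = FALSE)
  card <- list(card_id = card_id, title = as.character(title),
               sections = sections)
  class(card) <- "model_card"
  validate_card(card)
}

#' Construct a card section
#'
#' @param kind a section kind from [section_kinds()]
#' @param heading,body free text
#' @param annotations named list; allowed keys: note, description, date,
#'   source. A `date` must be ISO 8601 (YYYY-MM-DD, optional time).
#' @param children list of nested `card_section` objects; their kinds must be
#'   schema-valid parts of `kind` (see [allowed_children()])
#' @return object of class `card_section`
#' @export
card_section <- function(kind, heading = "", body = "",
                         annotations = list(), children = list()) {
  # canonical annotation order and character values, so that write -> read
  # round-trips are plain identical()
  known <- intersect(ANNOTATION_KEYS, names(annotations))
  annotations <- c(annotations[known],
                   annotations[setdiff(names(annotations), known)])
  annotations <- lapply(annotations, as.character)
  s <- list(kind = kind, heading = as.character(heading),
            body = as.character(body),
            annotations = annotations, children = children)
  class(s) <- "card_section"
  s
}

is_iso8601 <- function(x) {
  m <- regexec("^(\\d{4})-(\\d{2})-(\\d{2})([T ]\\d{2}:\\d{2}(:\\d{2})?)?$", x)
  parts <- regmatches(x, m)[[1]]
  if (!length(parts)) return(FALSE)
  !is.na(as.Date(paste(parts[2], parts[3], parts[4], sep = "-"),
                 format = "%Y-%m-%d"))
}

validate_section <- function(s, parent_kind, path) {
  if (!inherits(s, "card_section"))
    stop("section at ", path, " is not a card_section", call. = FALSE)
  if (!s$kind %in% section_kinds())
    stop("unknown section kind '", s$kind, "' at ", path,
         "; allowed kinds: ", paste(section_kinds(), collapse = ", "),
         call. = FALSE)
  ok <- allowed_children(parent_kind)
  if (!s$kind %in% ok)
    stop("section kind '", s$kind, "' is not a schema-valid part of '",
         parent_kind, "' at ", path,
         if (length(ok)) paste0(" (allowed: ", paste(ok, collapse = ", "), ")")
         else " (no children allowed)", call. = FALSE)
  bad <- setdiff(names(s$annotations), ANNOTATION_KEYS)
  if (length(bad))
    stop("unknown annotation key(s) at ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  d <- s$annotations$date
  if (!is.null(d) && !is_iso8601(d))
    stop("date annotation at ", path, " is not ISO 8601: '", d, "'",
         call. = FALSE)
  for (i in seq_along(s$children))
    validate_section(s$children[[i]], s$kind, paste0(path, "/", i))
  invisible(s)
}

#' Validate a model card against the schema's section vocabulary
#'
#' Checks kinds, nesting (children must be schema-valid parts of their
#' parent), annotation keys, and ISO 8601 dates. Returns the card invisibly;
#' problems raise errors naming the section path.
#'
#' @param card model_card
#' @return the card, invisibly
#' @export
validate_card <- function(card) {
  stopifnot(inherits(card, "model_card"))
  for (i in seq_along(card$sections))
    validate_section(card$sections[[i]], "ModelCardReport", paste0("/", i))
  invisible(card)
}

#' @export
print.model_card <- function(x, ...) {
  cat(sprintf("<model_card> %s: \"%s\" (%d top-level sections, %d total)\n",
              x$card_id, x$title, length(x$sections), count_sections(x)))
  invisible(x)
}

#' Count sections in a card, including nested ones
#' @param card model_card
#' @return integer
#' @export
count_sections <- function(card) {
  walk <- function(s) 1L + sum(vapply(s$children, walk, 0L))
  sum(vapply(card$sections, walk, 0L))
}

## ---- authoring format (YAML) ------------------------------------------

section_to_list <- function(s) {
  out <- list(kind = s$kind)
  if (nzchar(s$heading)) out$heading <- s$heading
  if (nzchar(s$body)) out$body <- s$body
  if (length(s$annotations)) {
    keep <- intersect(ANNOTATION_KEYS, names(s$annotations))
    out$annotations <- s$annotations[keep]
  }
  if (length(s$children))
    out$children <- lapply(s$children, section_to_list)
  out
}

section_from_list <- function(x, path) {
  if (is.null(x$kind))
    stop("section at ", path, " has no 'kind'", call. = FALSE)
  extra <- setdiff(names(x),
                   c("kind", "heading", "body", "annotations", "children"))
  if (length(extra))
    stop("unknown section field(s) at ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  ann <- x$annotations
  if (is.null(ann)) ann <- list()
  ann <- lapply(ann, function(v) as.character(v))
  card_section(kind = as.character(x$kind),
               heading = if (is.null(x$heading)) "" else x$heading,
               body = if (is.null(x$body)) "" else x$body,
               annotations = ann,
               children = lapply(seq_along(x$children), function(i)
                 section_from_list(x$children[[i]], paste0(path, "/", i))))
}

#' Serialize a model card to the authoring format
#'
#' The format is YAML, UTF-8, one card per document, with explicit `kind`
#' tags per section. [read_card()] of the output reproduces the card
#' field-for-field.
#'
#' @param card model_card
#' @param path optional file path; when given, the text is also written there
#' @return the document text, invisibly when `path` is given
#' @export
write_card <- function(card, path = NULL) {
  validate_card(card)
  doc <- list(card_id = card$card_id, title = card$title)
  if (length(card$sections))
    doc$sections <- lapply(card$sections, section_to_list)
  txt <- yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Read a model card from the authoring format
#'
#' @param input a file path or the document text itself
#' @return a validated model_card
#' @export
read_card <- function(input) {
  txt <- if (length(input) == 1L && !grepl("\n", input) &&
             file.exists(input)) {
    paste(readLines(input, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else paste(input, collapse = "\n")
  doc <- tryCatch(yaml::yaml.load(txt),
                  error = function(e)
                    stop("malformed card document: ", conditionMessage(e),
                         call. = FALSE))
  if (!is.list(doc) || is.null(doc$card_id) || is.null(doc$title))
    stop("malformed card document: card_id and title are required",
         call. = FALSE)
  sections <- lapply(seq_along(doc$sections), function(i)
    section_from_list(doc$sections[[i]], paste0("/sections/", i)))
  model_card(as.character(doc$card_id), as.character(doc$title), sections)
}

## ---- synthetic card generator -----------------------------------------

# run expr with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic model card
#'
#' Emulates realistic multi-section cards: sections are attached one at a
#' time to a uniformly chosen open slot (the card root or an existing section
#' whose kind allows children, below the depth limit), with the kind drawn
#' uniformly from the schema-valid child kinds of the attachment point. Every
#' section receives description and date annotations; deterministic for a
#' fixed seed.
#'
#' @param seed integer seed
#' @param n_sections total number of sections (>= 0)
#' @param depth maximum nesting depth (>= 1; 1 = only top-level sections)
#' @return model_card
#' @export
generate_card <- function(seed, n_sections, depth = 2L) {
  stopifnot(n_sections >= 0, depth >= 1)
  with_private_seed(seed, {
    slug <- sprintf("synthetic-card-%d", seed)
    # flat node store; parent 0 = card root
    nodes <- data.frame(kind = character(), parent = integer(),
                        depth = integer(), stringsAsFactors = FALSE)
    for (i in seq_len(n_sections)) {
      cand <- c(0L, which(nodes$depth < depth &
                          vapply(nodes$kind,
                                 function(k) length(allowed_children(k)) > 0L,
                                 TRUE)))
      at <- cand[[sample.int(length(cand), 1L)]]
      pkind <- if (at == 0L) "ModelCardReport" else nodes$kind[at]
      kinds <- allowed_children(pkind)
      kind <- kinds[[sample.int(length(kinds), 1L)]]
      d <- if (at == 0L) 1L else nodes$depth[at] + 1L
      nodes <- rbind(nodes, data.frame(kind = kind, parent = at, depth = d,
                                       stringsAsFactors = FALSE))
    }
    day <- sprintf("2022-%02d-%02d", sample.int(12, nrow(nodes), TRUE),
                   sample.int(28, nrow(nodes), TRUE))
    build <- function(i) {
      kids <- which(nodes$parent == i)
      card_section(
        kind = nodes$kind[i],
        heading = paste0(nodes$kind[i], " ", i),
        body = sprintf("Synthetic %s content (node %d).", nodes$kind[i], i),
        annotations = list(description = sprintf("synthetic section %d", i),
                           date = day[i]),
        children = lapply(kids, build))
    }
    top <- which(nodes$parent == 0L)
    model_card(slug, sprintf("Synthetic model card %d", seed),
               lapply(top, build))
  })
}
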
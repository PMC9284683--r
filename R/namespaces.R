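# Namespace table and CURIE handling. All external vocabulary the schema
# touches is resolved here, in one place.

#' Default prefix table
#'
#' Namespaces used by the model card report schema: the project namespace
#' (`mcro:`), an instance namespace for published card individuals (`mcri:`),
#' OBO Foundry PURLs (`obo:` for BFO/IAO terms), the Software Ontology
#' (`swo:`), SKOS, Dublin Core terms, PROV-O, and the RDF/OWL core.
#'
#' @return named character vector prefix -> namespace IRI
#' @export
default_prefixes <- function() {
  c(mcro    = "https://w3id.org/mcro#",
    mcri    = "https://w3id.org/mcro/instance/",
    obo     = "http://purl.obolibrary.org/obo/",
    swo     = "http://www.ebi.ac.uk/swo/",
    skos    = "http://www.w3.org/2004/02/skos/core#",
    dcterms = "http://purl.org/dc/terms/",
    prov    = "http://www.w3.org/ns/prov#",
    owl     = "http://www.w3.org/2002/07/owl#",
    rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
    xsd     = "http://www.w3.org/2001/XMLSchema#")
}

#' Expand a CURIE to an absolute IRI
#'
#' Strings that are already absolute IRIs (contain `://` or start with a
#' known non-prefix scheme like `urn:`) pass through unchanged. Unknown
#' prefixes are an error.
#'
#' @param x IRI or CURIE
#' @param prefixes named character vector
#' @return absolute IRI string
#' @export
expand_curie <- function(x, prefixes = default_prefixes()) {
  if (length(x) != 1L)
    return(vapply(x, expand_curie, "", prefixes = prefixes,
                  USE.NAMES = FALSE))
  if (is.na(x)) return(x)
  if (grepl("://", x, fixed = TRUE) || startsWith(x, "urn:")) return(x)
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", x))[[1]]
  if (length(m) == 3L) {
    ns <- unname(prefixes[m[2]])
    if (length(ns) != 1L || is.na(ns))
      stop("unknown CURIE prefix: ", m[2], call. = FALSE)
    return(paste0(ns, m[3]))
  }
  x
}

#' Compact an absolute IRI to a CURIE where a prefix matches
#'
#' The longest matching namespace wins; unmatched IRIs are returned unchanged.
#'
#' @param iri absolute IRI
#' @param prefixes named character vector
#' @return CURIE or the original IRI
#' @export
compact_iri <- function(iri, prefixes = default_prefixes()) {
  if (length(iri) != 1L)
    return(vapply(iri, compact_iri, "", prefixes = prefixes,
                  USE.NAMES = FALSE))
  if (is.na(iri)) return(iri)
  hits <- prefixes[startsWith(iri, prefixes)]
  if (!length(hits)) return(iri)
  ns <- hits[which.max(nchar(hits))]
  local <- substring(iri, nchar(ns) + 1L)
  # only compact when the local part is a valid prefixed-name local
  if (!grepl("^[A-Za-z0-9_]([A-Za-z0-9_.-]*[A-Za-z0-9_-])?$|^$", local))
    return(iri)
  paste0(names(ns), ":", local)
}

# Central constants table: every external term the schema references, with
# the resolved canonical identifier. Labels printed without IRIs in the
# source material (report, document part, part of, Collection, the Dublin
# Core annotation set) are pinned to their published identifiers here.
mcro_vocab <- list(
  # BFO / IAO object properties
  has_part        = list(curie = "obo:BFO_0000051", label = "has part",
                         category = "object-property"),
  part_of         = list(curie = "obo:BFO_0000050", label = "part of",
                         category = "object-property"),
  is_about        = list(curie = "obo:IAO_0000136", label = "is about",
                         category = "object-property"),
  # IAO classes
  ice             = list(curie = "obo:IAO_0000030",
                         label = "information content entity",
                         category = "class"),
  report          = list(curie = "obo:IAO_0000088", label = "report",
                         category = "class"),
  document_part   = list(curie = "obo:IAO_0000314", label = "document part",
                         category = "class"),
  data_set        = list(curie = "obo:IAO_0000100", label = "data set",
                         category = "class"),
  algorithm       = list(curie = "obo:IAO_0000064", label = "algorithm",
                         category = "class"),
  data_format     = list(curie = "obo:IAO_0000098",
                         label = "data format specification",
                         category = "class"),
  version_number  = list(curie = "obo:IAO_0000129", label = "version number",
                         category = "class"),
  reference_section = list(curie = "obo:IAO_0000320",
                           label = "reference section", category = "class"),
  graph_class     = list(curie = "obo:IAO_0000038", label = "graph",
                         category = "class"),
  citation        = list(curie = "obo:IAO_0000301", label = "citation",
                         category = "class"),
  # SWO
  software        = list(curie = "swo:SWO_0000001", label = "software",
                         category = "class"),
  license         = list(curie = "swo:SWO_0000002", label = "license",
                         category = "class"),
  # SKOS
  collection      = list(curie = "skos:Collection", label = "Collection",
                         category = "class"),
  # annotation properties
  alt_term        = list(curie = "obo:IAO_0000118", label = "alternative term",
                         category = "annotation-property"),
  note            = list(curie = "skos:note", label = "note",
                         category = "annotation-property"),
  description     = list(curie = "dcterms:description", label = "description",
                         category = "annotation-property"),
  date            = list(curie = "dcterms:date", label = "date",
                         category = "annotation-property"),
  source          = list(curie = "dcterms:source", label = "source",
                         category = "annotation-property"),
  title           = list(curie = "dcterms:title", label = "title",
                         category = "annotation-property")
)

#' The external vocabulary the schema is pinned to
#'
#' One row per external term used by the core schema, with its canonical
#' identifier, label and category. This is the single place where labels are
#' resolved to published IRIs.
#'
#' @return data frame with columns `key`, `curie`, `iri`, `label`, `category`
#' @export
vocab_table <- function() {
  p <- default_prefixes()
  data.frame(
    key = names(mcro_vocab),
    curie = vapply(mcro_vocab, `[[`, "", "curie"),
    iri = vapply(mcro_vocab, function(v) expand_curie(v$curie, p), ""),
    label = vapply(mcro_vocab, `[[`, "", "label"),
    category = vapply(mcro_vocab, `[[`, "", "category"),
    row.names = NULL, stringsAsFactors = FALSE)
}

# convenience: absolute IRI for a vocab key
vterm <- function(key) {
  expand_curie(mcro_vocab[[key]]$curie, default_prefixes())
}
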
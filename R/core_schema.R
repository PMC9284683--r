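# The core conceptual model for model card reports: a report class with four
# main sections (model parameters, considerations, model details,
# quantitative analysis), subsection classes, alignment axioms into OBO
# Foundry vocabularies, and the partonomy characteristics (has part is
# transitive, with part of as its declared inverse).

# MCRO-native classes, minted under the project namespace. The wiring table
# drives both the class-level has-part axioms and which section kinds may
# nest under which in authored cards.
mcro_sections <- list(
  ModelCardReport      = character(),   # children filled in below
  ModelParameters      = c("DatasetInformation", "ModelArchitecture",
                           "FormatInformation"),
  Considerations       = c("TradeOff", "EthicalConsideration"),
  ModelDetails         = c("VersionInformation", "ReferenceInformation",
                           "CitationInformation", "LicenseInformation",
                           "User"),
  QuantitativeAnalysis = c("Graphic", "GraphicCollection"),
  DatasetInformation   = character(),
  ModelArchitecture    = character(),
  FormatInformation    = character(),
  VersionInformation   = character(),
  ReferenceInformation = character(),
  CitationInformation  = character(),
  LicenseInformation   = character(),
  User                 = character(),
  TradeOff             = character(),
  EthicalConsideration = character(),
  Graphic              = character(),
  GraphicCollection    = c("Graphic")
)
MAIN_SECTIONS <- c("ModelParameters", "Considerations", "ModelDetails",
                   "QuantitativeAnalysis")
mcro_sections$ModelCardReport <- MAIN_SECTIONS

# human-readable labels for the minted classes
mcro_labels <- c(
  ModelCardReport = "Model Card Report",
  ModelParameters = "Model Parameters",
  Considerations = "Considerations",
  ModelDetails = "Model Details",
  QuantitativeAnalysis = "Quantitative Analysis",
  DatasetInformation = "Dataset Information",
  ModelArchitecture = "Model Architecture",
  FormatInformation = "Format Information",
  VersionInformation = "Version Information",
  ReferenceInformation = "Reference Information",
  CitationInformation = "Citation Information",
  LicenseInformation = "License Information",
  User = "User",
  TradeOff = "Trade Off",
  EthicalConsideration = "Ethical Consideration",
  Graphic = "Graphic",
  GraphicCollection = "Graphic Collection")

#' Section kinds known to the schema
#'
#' @param main_only return only the four main section kinds
#' @return character vector of section class local names
#' @export
section_kinds <- function(main_only = FALSE) {
  if (main_only) MAIN_SECTIONS
  else setdiff(names(mcro_sections), "ModelCardReport")
}

#' Schema-valid child kinds of a section kind
#'
#' Derived from the class-level has-part wiring of the schema: a section of
#' kind `kind` may nest exactly those subsections its class is linked to by a
#' has-part axiom. `"ModelCardReport"` gives the four main sections.
#'
#' @param kind a section kind or "ModelCardReport"
#' @return character vector (possibly empty)
#' @export
allowed_children <- function(kind) {
  if (!kind %in% names(mcro_sections))
    stop("unknown section kind: ", kind, call. = FALSE)
  mcro_sections[[kind]]
}

#' Build the core schema for model card reports
#'
#' Constructs, in memory, the conceptual model: the `ModelCardReport` class
#' (a subclass of the information-artifact *report* stub) with four main
#' sections — model parameters, considerations, model details, quantitative
#' analysis — each a *document part*, wired together with the *has part*
#' property (`obo:BFO_0000051`, declared transitive with inverse *part of*,
#' `obo:BFO_0000050`); subsection classes for dataset, architecture, format,
#' version, reference, citation, license, user, trade-off, ethical
#' consideration and graphics; alignment axioms into IAO/SWO (*is about*
#' links for dataset/architecture/format/version/license, equivalences for
#' reference section and graph, a has-part link from citation information to
#' *citation*); a SKOS `Collection` superclass for graphic collections; an
#' alternative-term annotation "Caveats" on the trade-off class; and a
#' disjointness axiom between the *software* and *algorithm* stubs.
#'
#' @param graphic_collection_link how the quantitative-analysis class links
#'   its graphic collection: `"has-part"` (default) or `"is-about"`. The
#'   source material leaves this edge open; it is exposed as a parameter.
#' @return a closed, consistent `ontology_graph`
#' @export
build_core_schema <- function(graphic_collection_link = c("has-part",
                                                          "is-about")) {
  graphic_collection_link <- match.arg(graphic_collection_link)
  g <- ontology_graph()
  g$ontology_iri <- "https://w3id.org/mcro"

  # external stub terms, from the central vocabulary table
  for (v in mcro_vocab)
    g <- add_term(g, v$curie, v$category, v$label)

  # minted section classes
  for (nm in names(mcro_sections))
    g <- add_term(g, paste0("mcro:", nm), "class", mcro_labels[[nm]])

  sub <- function(g, a, b) add_axiom(g, "subclass-of", a, object = b)
  opa <- function(g, s, p, o)
    add_axiom(g, "object-property-assertion", s, predicate = p, object = o)

  # IAO backbone stubs
  g <- sub(g, "obo:IAO_0000088", "obo:IAO_0000030")  # report < ICE
  g <- sub(g, "obo:IAO_0000314", "obo:IAO_0000030")  # document part < ICE

  # report alignment + section taxonomy
  g <- sub(g, "mcro:ModelCardReport", "obo:IAO_0000088")
  for (nm in section_kinds())
    g <- sub(g, paste0("mcro:", nm), "obo:IAO_0000314")
  g <- sub(g, "mcro:GraphicCollection", "skos:Collection")

  # partonomy wiring between section classes
  for (parent in names(mcro_sections)) {
    for (child in mcro_sections[[parent]]) {
      if (parent == "QuantitativeAnalysis" && child == "GraphicCollection" &&
          graphic_collection_link == "is-about") {
        g <- opa(g, "mcro:QuantitativeAnalysis", "obo:IAO_0000136",
                 "mcro:GraphicCollection")
      } else {
        g <- opa(g, paste0("mcro:", parent), "obo:BFO_0000051",
                 paste0("mcro:", child))
      }
    }
  }

  # alignment into IAO / SWO
  g <- opa(g, "mcro:DatasetInformation", "obo:IAO_0000136", "obo:IAO_0000100")
  g <- opa(g, "mcro:ModelArchitecture",  "obo:IAO_0000136", "obo:IAO_0000064")
  g <- opa(g, "mcro:FormatInformation",  "obo:IAO_0000136", "obo:IAO_0000098")
  g <- opa(g, "mcro:VersionInformation", "obo:IAO_0000136", "obo:IAO_0000129")
  g <- opa(g, "mcro:LicenseInformation", "obo:IAO_0000136", "swo:SWO_0000002")
  g <- add_axiom(g, "equivalent-class", "mcro:ReferenceInformation",
                 object = "obo:IAO_0000320")
  g <- add_axiom(g, "equivalent-class", "mcro:Graphic",
                 object = "obo:IAO_0000038")
  g <- opa(g, "mcro:CitationInformation", "obo:BFO_0000051", "obo:IAO_0000301")

  # characteristics of the partonomy property
  g <- add_axiom(g, "transitive-property", "obo:BFO_0000051")
  g <- add_axiom(g, "inverse-of", "obo:BFO_0000051", object = "obo:BFO_0000050")

  # alternative label: trade offs are also called caveats
  g <- add_axiom(g, "annotation-assertion", "mcro:TradeOff",
                 predicate = "obo:IAO_0000118", object = "Caveats",
                 literal = TRUE)

  # software and algorithm share no individuals
  g <- add_axiom(g, "disjoint-with", "swo:SWO_0000001", object = "obo:IAO_0000064")

  assert_closed(g)
}

#' Ontology metrics
#'
#' Counts classes, object properties, data properties and logical axioms.
#' Logical axioms are every axiom kind except declarations and
#' annotation assertions (the usual ontology-editor metric): subclass,
#' equivalence, disjointness, property characteristics, inverse, domain,
#' range, and all type/property assertions.
#'
#' @param g ontology_graph (must be closed)
#' @param check verify closure first
#' @return object of class `ontology_stats` with fields `n_classes`,
#'   `n_object_properties`, `n_data_properties`, `n_logical_axioms`
#' @export
ontology_stats <- function(g, check = TRUE) {
  if (check) assert_closed(g)
  s <- list(
    n_classes = sum(g$terms$category == "class"),
    n_object_properties = sum(g$terms$category == "object-property"),
    n_data_properties = sum(g$terms$category == "data-property"),
    n_logical_axioms = sum(g$axioms$kind %in% LOGICAL_KINDS))
  class(s) <- "ontology_stats"
  s
}

#' @export
print.ontology_stats <- function(x, ...) {
  cat(sprintf("classes: %d\nobject properties: %d\ndata properties: %d\nlogical axioms: %d\n",
              x$n_classes, x$n_object_properties, x$n_data_properties,
              x$n_logical_axioms))
  invisible(x)
}

#' @export
as.data.frame.ontology_stats <- function(x, ...) {
  data.frame(n_classes = x$n_classes,
             n_object_properties = x$n_object_properties,
             n_data_properties = x$n_data_properties,
             n_logical_axioms = x$n_logical_axioms)
}
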
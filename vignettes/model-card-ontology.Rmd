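---
title: "Representing model card reports as ontology instance graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing model card reports as ontology instance graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrotools)
```

## The representation

A model card report is a small structured document: a titled report with
sections for model details, model parameters, considerations (trade-offs,
ethics, intended users) and quantitative analysis. `mcrotools` encodes both
the *schema* of such documents and each *concrete card* in one container,
the `ontology_graph`: a set of terms (IRI, label, category), a set of
axioms, and a prefix table. Axioms have set semantics — duplicates are never
stored — and symmetric kinds (equivalence, disjointness) are normalized so
the lexicographically smaller IRI is the subject. Those two choices make
graph equality plain set equality and make every serialization byte-stable,
which in turn is what lets round-trip identity be asserted exactly rather
than up to isomorphism. Blank nodes are never emitted for the same reason.

The schema (`build_core_schema()`) places the model card report class under
the information-artifact *report* stub and the section classes under
*document part*, wires sections with *has part* (`obo:BFO_0000051`,
transitive, inverse *part of*), and aligns subsections to external
vocabulary via *is about*, two equivalences and one part link. External
terms are **stubs**: only the identifiers the schema actually touches are
declared, not the hundreds of classes of the source ontologies they come
from. Where the upstream documentation names a term only by its label
("report", "document part", "Collection"), the resolution to a canonical
identifier is recorded once, in `vocab_table()`: the annotation set
note/description/date/source maps to `skos:note` and the Dublin Core terms
`dcterms:description`/`date`/`source` (Dublin Core has no *note* term), the
alternative label "Caveats" on the trade-off class uses the OBO *alternative
term* annotation (`obo:IAO_0000118`), and the disjointness example pairs the
Software Ontology's *software* stub with the *algorithm* stub
(`obo:IAO_0000064`).

Two modelling points were genuinely open and are package decisions:

* **The quantitative-analysis → graphic-collection edge.** Whether a
  quantitative analysis *has part* or *is about* its graphic collection is
  not fixed by the card format. It is exposed as
  `build_core_schema(graphic_collection_link = )`, defaulting to
  `"has-part"` for uniformity with every other section edge.
* **Core size.** The published core of the ontology this package
  re-implements reports 38 classes, 11 data properties and 79 logical
  axioms; its exact class roster is not enumerable from the documentation.
  The constructed core (30 classes, 48 logical axioms) is a faithful
  approximation containing every identifier that *is* printed; it was not
  padded to hit the published totals. Likewise the published artifact
  attaches section text through bespoke data properties (*documentation*,
  *overview*, …); this package attaches text through the description
  annotation instead, which keeps the authoring format uniform, at the cost
  of an empty data-property count in the core metrics.

## Publishing cards

The authoring format is YAML, one card per file, with explicit `kind` tags
drawn from the schema's section classes; nesting validity is derived from
the schema's class-level has-part wiring, so the document model and the
ontology cannot drift apart. `to_instance_graph()` mints deterministic
identifiers — the card-id slug, plus per section a kind slug and a 6-hex-digit
FNV-1a hash of the section's position path — so re-publication is
reproducible and diffable. Section bodies become description annotations;
note/date/source only when supplied; dates must be ISO 8601
(`YYYY-MM-DD`, optional time), checked against base R's date parser.

## Reasoning

`materialize()` computes the least fixpoint of five rules: transitivity
(R1), inverses in both directions (R2), subclass transitivity (R3), type
inheritance (R4) and equivalence-as-mutual-subclass (R5). Class-level
closure (R5→R3→R4) is computed first by boolean reachability; property
closure alternates R2 and R1 until stable, which also closes the inverse of
a transitive property (its edge set is the transpose of a transitively
closed set). The rules are monotone over a finite term set, so termination
is structural, not tolerance-based; inferred axioms carry an `inferred`
flag and asserted axioms are never touched, giving idempotence and
monotonicity exactly.

The fragment is deliberately small: property chains, functional and
cardinality semantics are not implemented because nothing in the model card
schema uses them. They are **flagged** — the Turtle reader records such
constructs in `graph$unsupported` and warns — rather than silently dropped,
so a user reading a foreign ontology knows what the engine did not see.
`check_consistency()` reports one inconsistency per individual and unordered
disjoint class pair after materialization; because types are propagated
upward first, disjointness declared on superclasses is enforced on
subclasses without a separate inheritance rule.

## Serialization, extraction, validation, query

The Turtle writer sorts prefixes, subjects, predicates and objects in
C-locale (radix) order, so two calls are byte-identical; the reader supports
the dialect the writer produces (prefixed names, absolute IRIs, typed and
language-tagged literals, `a`, `;`/`,` lists) and classifies predicates from
declarations, falling back to structural inference for undeclared terms so
results are always closed. `xsd:string` datatypes are normalized away on
input since Turtle omits them on output. OWL/XML is write-only; its one
liberty is emitting schema-level property links between classes as property
assertions on the class IRIs.

`extract_subset()` implements the minimal *upward closure* flavor of
seed-based module extraction: seeds, their transitive superclass closure
(equivalence counts in both directions), properties used by retained
axioms, and exactly the axioms whose terms are all retained. One deliberate
extension: a retained property drags in its declared inverse, so partonomy
semantics survive extraction. Richer, entailment-preserving module
extraction methods exist; the variant here is documented as an
approximation sufficient for producing importable slices.

`validate_instances()` applies five structural rules (reachability of
section individuals from a report via asserted has-part; domain/range after
materialization; ISO-8601 dates; report completeness; disjointness). A
report with no sections is an error; an absent main section is only a
warning, because sample cards are understood to *cover*, not *mandate*, all
four mains. `match_triples()` is single-pattern matching only — with
`infer = TRUE` it runs against the materialized graph — the smallest
facility that demonstrates inference-aware search; joins and a full query
language are out of scope.

## What the synthetic generator does and does not emulate

`generate_card(seed, n_sections, depth)` grows a card by repeatedly
attaching a new section to a uniformly chosen open slot (root or an
existing section whose kind admits children, below the depth cap), drawing
the kind uniformly from the schema-valid child kinds; every section gets
description and date annotations. This emulates the *structure* of real
multi-section cards — nested part-whole trees with per-section annotations —
and drives the round-trip, publication and validation property tests. It
does not emulate realistic text, skewed section-frequency distributions, or
malformed input (defect tests plant those explicitly), so a passing
property suite certifies structural correctness of the pipeline, not
robustness to arbitrary real-world documents.

Problem sizes in the test and acceptance runs are the package's own
choices: 200 random partonomy graphs of at most 10 individuals for the
reasoner properties (closure checked against a breadth-first-search oracle
written independently of the matrix-based engine), 200 random mixed graphs
for Turtle round-trips, 50 of each re-checked by `scripts/acceptance.R` at
every run, and generated cards of up to 50 sections at depth 3. At these
sizes the whole suite runs in well under a minute.

## Known limitations

* The reasoner is a rule engine over named terms, not a tableau reasoner:
  no complex class expressions, no satisfiability of the TBox itself.
* The Turtle reader covers the package's dialect; RDF/XML, N-Triples,
  JSON-LD and blank-node class expressions are out of scope (the latter are
  recorded as unsupported on read).
* Reproducing the published artifact's full feature counts (954 classes,
  2147 logical axioms) requires that artifact as input; it is far larger
  than the fixtures bundled here, so the corresponding check only runs when
  a local copy is supplied via the `mcrotools.published_artifact` option.
* Cycles in a partonomy are not an error for the reasoner (the closure is
  still finite) but published cards always produce trees; the validator's
  reachability rule assumes tree-like instance data.
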
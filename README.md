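# mcrotools

Model card reports are short structured documents that describe a machine
learning model for its stakeholders: what the model is, what data and
algorithm it is built on, its quantitative performance, and the ethical
considerations and trade-offs around its use. As static text they cannot be
indexed, aggregated or reasoned over. `mcrotools` turns model cards into
**OWL2 ontology instance graphs**: each card becomes a typed individual
whose sections hang off it through the OBO Foundry part-whole relation, so
that standard semantic-web machinery — inference, consistency checking,
triple-pattern search — applies to the card's content.

The package is aimed at biomedical informaticians and ontology engineers who
want machine-readable model cards aligned with the OBO Foundry ecosystem
(BFO, the Information Artifact Ontology, the Software Ontology, PROV-O,
SKOS).

## The model

The core schema models a model card report as a subclass of the
information-artifact *report* concept, with four main sections — *Model
Parameters*, *Considerations*, *Model Details*, *Quantitative Analysis* —
each a *document part*, plus subsection classes (dataset, architecture,
format, version, reference, citation, license, user, trade-off, ethical
consideration, graphics). Sections are wired together with the *has part*
property (`obo:BFO_0000051`), declared **transitive** with declared inverse
*part of* (`obo:BFO_0000050`). Subsections align outward: *is about*
(`obo:IAO_0000136`) links dataset/architecture/format/version/license
sections to `obo:IAO_0000100` (data set), `obo:IAO_0000064` (algorithm),
`obo:IAO_0000098` (data format specification), `obo:IAO_0000129` (version
number) and `swo:SWO_0000002` (license); reference and graphic sections are
equivalent to `obo:IAO_0000320` (reference section) and `obo:IAO_0000038`
(graph); citation sections have `obo:IAO_0000301` (citation) parts.

Publishing a card instantiates this schema; the bundled reasoner then
materializes the fixpoint of five rules:

```
R1  p transitive ∧ ⟨a p b⟩ ∧ ⟨b p c⟩  ⇒  ⟨a p c⟩
R2  p inverse-of q ∧ ⟨a p b⟩          ⇒  ⟨b q a⟩      (both directions)
R3  A ⊑ B ∧ B ⊑ C                     ⇒  A ⊑ C
R4  ⟨x type A⟩ ∧ A ⊑ B                ⇒  ⟨x type B⟩
R5  A ≡ B                             ⇒  A ⊑ B ∧ B ⊑ A
```

Consistency checking reports every individual typed by two disjoint classes
(e.g. *software* vs *algorithm*, which the schema declares disjoint),
including disjointness inherited through subclasses.

## Worked example

```r
library(mcrotools)

schema <- build_core_schema()
ontology_stats(schema)
#> classes: 30
#> object properties: 3
#> data properties: 0
#> logical axioms: 48

card <- read_card(system.file("extdata", "cards",
                              "pci-adverse-endpoints.yaml",
                              package = "mcrotools"))
card
#> <model_card> pci-adverse-endpoints: "Adverse endpoints prediction for
#>  patients undergoing PCI" (4 top-level sections, 13 total)

g <- to_instance_graph(card)        # schema + 14 typed individuals
m <- materialize(g)
sum(m$axioms$inferred)
#> [1] 135

# inference-aware search: all parts of the card, beyond the first degree
nrow(match_triples(g, "mcri:pci-adverse-endpoints", "obo:BFO_0000051",
                   NULL, infer = TRUE))
#> [1] 13

check_consistency(m)
#> consistent: no disjointness violations
validate_instances(g)
#> valid: no findings
```

The card has 13 sections but only 4 direct parts; transitivity of *has
part* makes all 13 reachable from the card individual, and the inverse rule
adds the corresponding *part of* edges. The 135 inferred axioms are those
closure edges plus inherited types and subclass links. Zero
inconsistencies and zero validation findings mean the published card
satisfies the schema's logical and structural constraints.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/mcro.R author inst/extdata/cards/pci-adverse-endpoints.yaml -o pci.ttl
Rscript inst/cli/mcro.R reason pci.ttl --check      # exit 0: consistent
Rscript inst/cli/mcro.R stats pci.ttl               # 30 3 0 75
Rscript inst/cli/mcro.R query pci.ttl mcri:pci-adverse-endpoints obo:BFO_0000051 '?' --infer
```

(after installation the script is at `system.file("cli", "mcro.R", package
= "mcrotools")`). Graphs serialize deterministically to Turtle (`.ttl`,
read/write) and OWL/XML (`.owl`, write-only); `extract` produces seed-based
subsets (seed terms plus their superclass closure) for lightweight imports.

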
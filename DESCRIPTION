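Package: mcrotools
Title: Authoring, Reasoning and Validation of Machine-Readable Model Card Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for representing machine learning model card reports as
    OWL2 ontology instance graphs. Builds the core conceptual schema for model
    card reports (four main sections aligned to OBO Foundry information
    artifact terms), reads and writes a structured card authoring format,
    publishes cards as instance graphs, materializes rule-based inferences
    (transitive and inverse partonomy, subclass and type propagation), checks
    disjointness consistency, validates instance graphs against the schema,
    extracts seed-based ontology subsets, computes ontology metrics, and
    serializes graphs to Turtle and OWL/XML.
License: MIT
Encoding: UTF-8
Imports:
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
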
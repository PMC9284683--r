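card_id: hiv-social-network
title: Incorporating social network information to predict HIV status
sections:
  - kind: ModelDetails
    heading: Model details
    body: >-
      A graph convolutional network that predicts HIV infection status from
      social network survey data among young MSM.
    annotations:
      date: "2022-07-14"
    children:
      - kind: User
        heading: Developers and owners
        body: Bioinformatics research group studying HIV transmission networks.
      - kind: CitationInformation
        heading: How to cite
        body: Cite the accompanying methods publication.
  - kind: ModelParameters
    heading: Model parameters
    body: Assembly of the model.
    children:
      - kind: ModelArchitecture
        heading: Architecture
        body: Graph convolutional network over the social contact graph.
      - kind: DatasetInformation
        heading: Training data
        body: Social network survey data with partially observed HIV status.
  - kind: Considerations
    heading: Considerations
    body: Limits, caveats and impact on intended users.
    children:
      - kind: TradeOff
        heading: Trade-offs
        body: >-
          Sparse or incomplete network data reduces predictive performance;
          network information can leak sensitive membership signals.
      - kind: EthicalConsideration
        heading: Ethical considerations
        body: >-
          Network-derived predictions concern a stigmatized condition and
          must be handled under strict confidentiality.
  - kind: QuantitativeAnalysis
    heading: Quantitative analysis
    body: Performance on held-out survey waves.
    children:
      - kind: GraphicCollection
        heading: Performance figures
        body: Figures summarizing discrimination and calibration.
        children:
          - kind: Graphic
            heading: ROC curve
            body: Receiver operating characteristic on the evaluation split.
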
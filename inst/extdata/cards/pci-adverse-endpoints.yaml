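card_id: pci-adverse-endpoints
title: Adverse endpoints prediction for patients undergoing PCI
sections:
  - kind: ModelDetails
    heading: Model details
    body: >-
      A recurrent neural network model for prediction of adverse outcomes
      from coronary artery stent implantation, trained on electronic health
      record data.
    annotations:
      description: General information about the model.
      date: "2022-07-14"
      source: University of Texas Health Science Center
    children:
      - kind: User
        heading: Developers and owners
        body: >-
          Developed and maintained by a bioinformatics research group working
          on machine learning models over EHR data.
      - kind: VersionInformation
        heading: Version
        body: Version 1.0, initial release.
      - kind: LicenseInformation
        heading: License
        body: Released for research use.
  - kind: ModelParameters
    heading: Model parameters
    body: Assembly of the model.
    children:
      - kind: ModelArchitecture
        heading: Architecture
        body: Recurrent neural network over longitudinal patient records.
      - kind: DatasetInformation
        heading: Training data
        body: >-
          De-identified electronic health records of patients undergoing
          percutaneous coronary intervention.
      - kind: FormatInformation
        heading: Input and output format
        body: Tabular longitudinal features in; adverse-endpoint risk out.
  - kind: Considerations
    heading: Considerations
    body: Limits, caveats and impact on intended users.
    annotations:
      note: Reviewed by the model owners.
    children:
      - kind: TradeOff
        heading: Trade-offs
        body: >-
          Model performance degrades on patient populations that are
          under-represented in the training records.
      - kind: EthicalConsideration
        heading: Ethical considerations
        body: >-
          Predictions must not be used as the sole basis for clinical
          decisions.
  - kind: QuantitativeAnalysis
    heading: Quantitative analysis
    body: Performance of the model on held-out data.
    children:
      - kind: Graphic
        heading: Calibration plot
        body: Calibration of predicted against observed event rates.
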
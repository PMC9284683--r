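# Seed terms for subset extraction: the external alignment targets of the
# model card schema (one IRI or CURIE per line; '#' starts a comment).
obo:IAO_0000100   # data set
obo:IAO_0000064   # algorithm
obo:IAO_0000098   # data format specification
obo:IAO_0000129   # version number
obo:IAO_0000320   # reference section
obo:IAO_0000038   # graph
obo:IAO_0000301   # citation
swo:SWO_0000002   # license
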
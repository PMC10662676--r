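# Default self-reported diagnosis disclosure patterns. Each template's
# {DX} slot is filled with every synonym. Larger pattern batteries are
# study-specific configuration; extend this file for your own cohort.
templates:
  - "I was diagnosed with {DX}"
  - "I have been diagnosed with {DX}"
  - "I am diagnosed with {DX}"
  - "I got diagnosed with {DX}"
  - "my {DX} diagnosis"
dx_synonyms:
  - "bipolar disorder"
  - "bipolar"
  - "bd"
  - "manic depression"
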
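id: Q7
description: distinct variants per chromosome over all samples
levels: [raw]
params:
  {}
templates:
  raw: sql/Q7_raw.sql
postprocess: ~
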
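id: Q6
description: occurrence counts per substitution type over all samples
levels: [raw]
params:
  {}
templates:
  raw: sql/Q6_raw.sql
postprocess: ~
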
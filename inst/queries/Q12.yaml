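id: Q12
description: variant counts per chromosome for a given sample
levels: [raw]
params:
  sample_id: ~
templates:
  raw: sql/Q12_raw.sql
postprocess: ~
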
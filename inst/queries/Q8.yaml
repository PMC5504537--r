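id: Q8
description: records with alt-read fraction above 90 percent for one sample
levels: [raw]
params:
  sample_id: ~
templates:
  raw: sql/Q8_raw.sql
postprocess: ~
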
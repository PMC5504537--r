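id: Q9
description: het/hom ratio on chromosome X for one sample
levels: [raw]
params:
  sample_id: ~
templates:
  raw: sql/Q9_raw.sql
postprocess: ~
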
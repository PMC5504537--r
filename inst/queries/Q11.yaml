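id: Q11
description: distinct genes containing variants, per sample
levels: [raw]
params:
  source: ensembl
templates:
  raw: sql/Q11_raw.sql
postprocess: ~
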
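id: Q10
description: variant counts per sample for a given chromosome
levels: [raw]
params:
  chrom: ~
templates:
  raw: sql/Q10_raw.sql
postprocess: ~
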
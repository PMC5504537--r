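id: Q5
description: all variants of one sample in a genomic range
levels: [raw]
params:
  sample_id: ~
  chrom: ~
  start: ~
  end: ~
templates:
  raw: sql/Q5_raw.sql
postprocess: ~
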
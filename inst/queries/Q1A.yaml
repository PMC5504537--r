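id: Q1A
description: per-variant allele frequency by continental region
levels: [raw, aggr, aggr_denorm]
params:
  {}
templates:
  raw: sql/Q1A_raw.sql
  aggr: sql/Q1A_aggr.sql
  aggr_denorm: sql/Q1A_denorm.sql
postprocess: ~
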
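id: Q1B
description: per-variant allele frequency by country
levels: [raw, aggr, aggr_denorm]
params:
  {}
templates:
  raw: sql/Q1B_raw.sql
  aggr: sql/Q1B_aggr.sql
  aggr_denorm: sql/Q1B_denorm.sql
postprocess: ~
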
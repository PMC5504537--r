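id: Q4A
description: depth-of-coverage five-number summary per canonical transcript
levels: [raw, aggr, aggr_denorm]
params:
  source: ensembl
templates:
  raw: sql/Q4A_raw.sql
  aggr: sql/Q4A_aggr.sql
  aggr_denorm: sql/Q4A_denorm.sql
postprocess: dp_quantiles
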
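id: Q4B
description: depth-of-coverage five-number summary per merged-transcript exon
levels: [raw, aggr, aggr_denorm]
params:
  source: ensembl
templates:
  raw: sql/Q4B_raw.sql
  aggr: sql/Q4B_aggr.sql
  aggr_denorm: sql/Q4B_denorm.sql
postprocess: dp_quantiles
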
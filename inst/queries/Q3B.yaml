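id: Q3B
description: variant-call counts in a disease subpopulation per merged-transcript exon
levels: [raw, aggr, aggr_denorm]
params:
  omim_id: ~
  source: ensembl
templates:
  raw: sql/Q3B_raw.sql
  aggr: sql/Q3B_aggr.sql
  aggr_denorm: sql/Q3B_denorm.sql
postprocess: ~
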
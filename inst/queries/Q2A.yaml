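id: Q2A
description: count and cumulative AF of rare damaging variants per canonical transcript
levels: [raw, aggr, aggr_denorm]
params:
  af_cutoff: 0.01
  damaging_only: 1
  source: ensembl
templates:
  raw: sql/Q2A_raw.sql
  aggr: sql/Q2A_aggr.sql
  aggr_denorm: sql/Q2A_denorm.sql
postprocess: ~
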
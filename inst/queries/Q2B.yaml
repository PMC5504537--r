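id: Q2B
description: count and cumulative AF of rare damaging variants per merged-transcript exon
levels: [raw, aggr, aggr_denorm]
params:
  af_cutoff: 0.01
  damaging_only: 1
  source: ensembl
templates:
  raw: sql/Q2B_raw.sql
  aggr: sql/Q2B_aggr.sql
  aggr_denorm: sql/Q2B_denorm.sql
postprocess: ~
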
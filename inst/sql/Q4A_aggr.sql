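SELECT d.transcript_id AS transcript_id, f.dp AS dp, SUM(f.n) AS n
FROM fact_agg_depth f
JOIN {{dim_gp}} d
  ON d.chrom = f.chrom AND f.pos BETWEEN d."start" AND d."end"
WHERE d.is_canonical = 1
GROUP BY d.transcript_id, f.dp
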
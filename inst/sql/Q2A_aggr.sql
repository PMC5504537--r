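WITH vaf AS (
  SELECT chrom, pos, ref, alt, prediction_fk,
         (SUM(n_het) + 2 * SUM(n_homalt)) * 1.0
           / (2.0 * (SELECT COUNT(*) FROM samples)) AS af
  FROM fact_agg_counts
  GROUP BY chrom, pos, ref, alt, prediction_fk
)
SELECT d.transcript_id AS transcript_id, COUNT(*) AS n_variants, SUM(v.af) AS cum_af
FROM vaf v
JOIN dim_variant_predictions p ON p.prediction_fk = v.prediction_fk
JOIN {{dim_gp}} d
  ON d.chrom = v.chrom AND v.pos BETWEEN d."start" AND d."end"
WHERE d.is_canonical = 1
  AND v.af < ?af_cutoff
  AND (?damaging_only = 0 OR p.fathmm_damaging = 1)
GROUP BY d.transcript_id
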
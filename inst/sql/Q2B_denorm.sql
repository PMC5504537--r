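WITH vaf AS (
  SELECT chrom, pos, ref, alt, MAX(fathmm_damaging) AS dmg,
         (SUM(n_het) + 2 * SUM(n_homalt)) * 1.0
           / (2.0 * (SELECT COUNT(*) FROM samples)) AS af
  FROM fact_agg_counts_dims
  GROUP BY chrom, pos, ref, alt
)
SELECT d.transcript_id AS transcript_id, d.exon_number AS exon_number, d."start" AS exon_start, d."end" AS exon_end, COUNT(*) AS n_variants, SUM(v.af) AS cum_af
FROM vaf v
JOIN {{dim_gp}} d
  ON d.chrom = v.chrom AND v.pos BETWEEN d."start" AND d."end"
WHERE d.is_merged = 1
  AND v.af < ?af_cutoff
  AND (?damaging_only = 0 OR v.dmg = 1)
GROUP BY d.transcript_id, d.exon_number, d."start", d."end"
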
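SELECT d.transcript_id AS transcript_id, d.exon_number AS exon_number, d."start" AS exon_start, d."end" AS exon_end, SUM(f.n_het + f.n_homalt) AS n_records
FROM fact_agg_counts f
JOIN dim_disease dd ON dd.disease_id = f.disease_fk
JOIN {{dim_gp}} d
  ON d.chrom = f.chrom AND f.pos BETWEEN d."start" AND d."end"
WHERE d.is_merged = 1
  AND dd.omim_id = ?omim_id
GROUP BY d.transcript_id, d.exon_number, d."start", d."end"
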
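SELECT f.sample_id AS sample_id, COUNT(DISTINCT d.gene_symbol) AS n_genes
FROM fact f
JOIN {{dim_gp}} d
  ON d.chrom = f.chrom AND f.pos BETWEEN d."start" AND d."end"
WHERE d.is_merged = 1
GROUP BY f.sample_id
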
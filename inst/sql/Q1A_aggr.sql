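WITH denom AS (
  SELECT g.region AS region, COUNT(*) AS n_samples
  FROM samples s JOIN dim_geography g ON s.geo_fk = g.geo_id
  GROUP BY g.region
),
counts AS (
  SELECT f.chrom, f.pos, f.ref, f.alt, g.region AS region,
         SUM(f.n_het) AS n_het, SUM(f.n_homalt) AS n_homalt
  FROM fact_agg_counts f JOIN dim_geography g ON f.geo_fk = g.geo_id
  GROUP BY f.chrom, f.pos, f.ref, f.alt, g.region
),
variants AS (SELECT DISTINCT chrom, pos, ref, alt FROM fact_agg_counts)
SELECT v.chrom AS chrom, v.pos AS pos, v.ref AS ref, v.alt AS alt,
       d.region AS region,
       (COALESCE(c.n_het, 0) + 2 * COALESCE(c.n_homalt, 0)) * 1.0
         / (2.0 * d.n_samples) AS af
FROM variants v
CROSS JOIN denom d
LEFT JOIN counts c
  ON c.chrom = v.chrom AND c.pos = v.pos AND c.ref = v.ref AND c.alt = v.alt
 AND c.region = d.region
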
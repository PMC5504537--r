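SELECT chrom, COUNT(DISTINCT pos || ':' || ref || ':' || alt) AS n
FROM fact
GROUP BY chrom
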
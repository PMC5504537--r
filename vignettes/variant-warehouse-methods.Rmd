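---
title: "Methods: simulating, warehousing and benchmarking genomic variant cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, warehousing and benchmarking genomic variant cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varwarehouse)
```

## What this package models

Population-scale exome projects hold genotype calls for tens of thousands of
samples, and the analytical questions asked of them — allele frequencies per
sub-population, cumulative frequencies of rare damaging variants per exon,
case/control enrichment, depth-of-coverage profiles — are classic OLAP
workloads. `varwarehouse` is a desk-scale benchmarking suite for that
workload: it generates a synthetic but statistically faithful cohort, stores
it as a star schema at several physical optimization levels, runs twelve
parameterized biomedical SQL queries through an embedded engine, verifies
every answer against an independent in-memory oracle, and times the runs.

Because no public resource releases per-sample genotypes at this scale, all
inputs are synthetic. The generators emulate the *shape* of the real
resources — a dbNSFP/ExAC-like variant catalog with per-ethnic-group allele
frequencies and a deleteriousness flag, Ensembl/RefSeq-like exon tables, a
geography hierarchy, an OMIM-like disease list — without containing a single
byte of them.

## The cohort model

### Genotypes

Every sample belongs to one of four ethnic groups (EUR, AMR, EAS, AFR), and
every catalog variant carries one allele frequency per group. Conditional on
the group frequency $af$, a sample's genotype at that site is drawn from the
Hardy–Weinberg probabilities

$$p(0/0) = 1 - 2\,af + af^2,\qquad p(0/1) = 2\,af\,(1-af),\qquad p(1/1) = af^2,$$

implemented verbatim in `genotype_probabilities()`. Draws are independent
across sites and samples; linkage, inbreeding and relatedness are not
modeled. Only non-reference calls enter the fact table — at cohort scale the
fact cardinality implies variant-site rows only — so allele-frequency
denominators always come from the sample registry ($2N$ per group), never
from counting fact rows.

### Allele frequencies

The paper-scale resources read their frequencies from ExAC; a synthetic
catalog needs a generative law instead. Each variant draws a base frequency
from a right-skewed Beta(0.3, 6) (mean ≈ 0.048, most variants rare — the
regime where rarity filters and 1% cutoffs are meaningful), then each
group's frequency is the base jittered on the logit scale with sd 0.5.
Jittering a shared base gives positive cross-group correlation, which is
what makes "rare in every sub-population" a nontrivial predicate. Both
hyperparameters sit in `af_hyperparams()`; `fixed =` short-circuits the
model for degenerate fixtures (all-zero, all-one, all-0.5 frequencies).

### Geography and diseases

Regions map 1:1 onto ethnic groups (Europe→EUR, Americas→AMR, Asia→EAS,
Africa→AFR); the hierarchy region → subregion → country is strictly
functional. Country populations are log-normal (meanlog log(8·10⁶), sdlog
1.6), heavy-tailed enough that population-weighted country assignment is a
real multinomial, not a uniform draw. A sample carries a disease label with
configurable prevalence, uniform over the disease dimension; how disease
labels attach to samples is a free design axis here, and prevalence is
deliberately a knob rather than a constant.

### Gene models

Both annotation sources realize transcript structure over a shared latent
exon layout derived from the seed alone: genes are placed without overlap
on length-weighted chromosomes, each with 1 + Poisson exons of log-normal
length. Per source, each gene gets a canonical transcript spanning all
exons, optionally an alternative transcript over a subset, and exactly one
merged transcript covering the union of the gene's exons. The refseq source
pads exon bounds by a 10 bp flank. Sharing the latent layout is what
guarantees the containment invariant — every catalog variant falls inside a
merged exon of *both* sources — which fully independent models could not
provide; the flank keeps the two dimension tables from being byte-identical
so both interval joins are genuinely exercised.

### Depth of coverage

Per site, the catalog fixes a mean depth (Gamma, shape 8, mean 60× — typical
exome coverage). A call's total depth is Poisson at that mean; alt-supporting
reads are Binomial(dp, ½) for heterozygotes and dp − Binomial(dp, ε) with
ε = 0.01 for alt homozygotes. Genotype-likelihood fields are carried as
nullable placeholders and never simulated. `0 ≤ ad_alt ≤ dp` holds by
construction.

## The warehouse

The star schema has one fact table (one row per non-reference genotype
call, with foreign keys into geography, both gene-model sources, disease
and predictor dimensions) and is materialized at four levels:

* **raw** — the fact table, Parquet, partitioned by chromosome and sorted
  by (chrom, ref, alt, sample_id) inside partitions: low-cardinality
  leading columns compress well.
* **aggr** — `fact_agg_counts`, one row per (variant × country × disease)
  with het/hom-alt counts and all FKs, plus an artificial surrogate key.
  Depth quantiles cannot be recomputed from genotype counts, so the level
  also stores `fact_agg_depth`, the exact per-group depth histogram
  (group keys + dp + n). This is what lets the depth query return
  *identical* answers at every level rather than approximations.
* **aggr_denorm** — the same two tables with every FK replaced by the
  dimension attributes (wide, join-free for geography/disease slicing).
* **cube** — an embedded key-value materialization of group-bys along
  declared hierarchy prefixes (geography region→subregion→country; gene→
  transcript→exon), with counts, allele counts and distinct-variant
  measures. Undeclared grouping patterns return an explicit reroute signal
  so callers fall back to level 3 — the cube accelerates, it never guesses.

Parquet is the mandatory format; Feather (Arrow IPC) is the second
columnar format behind the same writer interface for format-comparison
studies, and the compression codec (`none`, `snappy`, `gzip`) is a
configuration axis. A JSON catalog file stands in for a metastore.

## The query suite and its oracles

Twelve query types (sixteen with A/B subqueries) ship as SQL text templates
with named placeholders and one YAML descriptor each. Binding goes through
`DBI::sqlInterpolate()`, so parameters are values, never spliced strings.
Conventions that the oracles pin down exactly:

* AF denominator = 2 × samples in the group from the registry; a variant
  absent from a group has AF 0, and the per-variant × per-group grid is
  explicit in the result.
* Rarity (Q2) is judged on the overall cohort AF, cutoff parameterized,
  default 0.01; the damaging filter can be switched off.
* A-subqueries group by canonical transcripts, B-subqueries by exons of
  merged transcripts; membership is point containment
  `pos ∈ [start, end]` through an interval join, so a variant counts once
  per containing transcript/exon.
* Disease filtering uses the OMIM id (a unique dimension attribute) at
  every level, so one parameter set renders across levels.
* Depth quantiles use linear interpolation between closest ranks
  (`stats::quantile` type 7). SQLite has no quantile aggregate, so the
  engine templates return per-group depth histograms and the adapter
  post-processes them; the oracle computes the same quantiles from raw
  depth vectors, keeping the two routes independent.
* Substitution types (Q6) are not collapsed to strand-equivalence classes
  by default; `collapse_substitutions()` provides the folded view.
* Q3 counts fact records (calls); allele counting is available through the
  returned het/hom split at aggregated levels.
* Results are compared after sorting on exact (non-floating) key columns
  only, with 1e-9 relative tolerance on real measures, so tiny numeric
  differences can never permute rows into false mismatches.

The oracles are deliberately primitive: base-R loops, `rowsum`, `tapply`,
interval scans. They share no code path with the SQL templates or the
engine adapter.

## The harness

`run_bench()` expands (query × engine × format × codec × level) from a YAML
config, executes each combination a configured number of repetitions
(default 5), and records wall seconds and result cardinality per run. A
failing combination is recorded with status `failed` and the run continues;
with verification on, a cardinality divergence from the oracle flags the
row `mismatch` — correctness dominates timing. Summaries report mean/min/max
per combination (all-failed combinations are flagged and excluded from
means), and the figures draw grouped bars with min/max error bars, one
figure per query family. Timings here are warm: an OS cache purge between
runs is a platform-specific operation that the harness does not perform, so
absolute numbers characterize the embedded engine on warm caches only.

## Problem sizes and what the tests show

The standard fixture used throughout the tests and the acceptance script is
200 samples × 5 000 catalog variants over 181 countries, 100 genes and 25
diseases (uniform ethnic proportions, disease prevalence 0.3) — about 90 000
fact rows, small enough that every query can also be answered by brute
force in memory, which is the entire point: at this scale the oracle is
feasible and the engine is checkable. Statistical calibration (recovery of
catalog allele frequencies with regression slope 1 ± 0.02, 4σ binomial
coverage ≥ 99%, depth-model fractions) holds at this size with comfortable
margins.

Passing these checks shows that the machinery — generators, storage levels,
SQL, oracles, harness — is internally consistent and statistically
calibrated. It does not show that real cohorts look like this: real variant
data has linkage, indels and multi-allelic sites, batch effects in depth,
non-uniform ethnic composition, and allele-frequency spectra with far
heavier rare tails. Distributed-engine behavior (network shuffles, memory
pressure, cost-based planning) is explicitly out of scope; the embedded
engine measures query semantics and relative storage-level effects, not
cluster performance.

## Known limitations

* SNVs only; no indels, multi-allelic sites, phasing, CNV calls or
  genotype likelihoods.
* One embedded engine (SQLite dialect); the adapter contract is pluggable
  but no remote adapters ship.
* The cube is rebuilt in memory from level 3 rather than incrementally
  maintained.
* Catalog size is a free parameter: nothing in the emulated resources pins
  how many variants the reference catalog should hold, so it is chosen per
  study (5 000 in the standard fixture).
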
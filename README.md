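# varwarehouse

Star-schema warehousing and query benchmarking for genomic variant cohorts,
at desk scale.

Population-scale exome projects store one genotype call per (sample,
variant) — billions of rows — and the questions asked of them are analytical:
allele frequencies broken down by population hierarchy, cumulative
frequencies of rare damaging variants per transcript or exon, variant
enrichment in disease subcohorts, depth-of-coverage profiles, per-sample
range browsing. `varwarehouse` is for people designing such variant data
warehouses: it provides a seeded synthetic cohort generator, a star schema
materialized at four physical storage levels, twelve parameterized
biomedical SQL queries with independent in-memory reference oracles, and an
automated timing harness — so that storage-level and query-design decisions
can be tested for *correctness* and *relative cost* before any cluster is
involved.

## The model in brief

Each sample belongs to one of four ethnic groups (EUR, AMR, EAS, AFR) and
to a country drawn within its group's region with probability proportional
to population size. Each catalog variant carries a per-group allele
frequency *af*; a sample's genotype at that site is drawn under
Hardy–Weinberg equilibrium:

    p(0/0) = 1 − 2·af + af²     p(0/1) = 2·af·(1 − af)     p(1/1) = af²

Only non-reference calls are stored in the fact table; allele-frequency
denominators (2N per group) come from the sample registry. Total depth per
call is Poisson at the site mean; alt-supporting reads are Binomial(dp, ½)
for heterozygotes and dp − Binomial(dp, ε) for alt homozygotes.

The warehouse levels are: `raw` (the fact table, Parquet, partitioned by
chromosome), `aggr` (per-variant × country × disease genotype counts plus
an exact depth histogram), `aggr_denorm` (the same, with every foreign key
replaced by dimension attributes), and a materialized-aggregate `cube` over
declared hierarchies with an explicit reroute signal for undeclared
patterns. Queries Q1–Q4 (A/B subqueries: canonical transcripts vs merged
exons) run on all three table levels and must return identical answers;
Q5–Q12 run on the fact table. The embedded SQL engine is SQLite via DBI;
every result is checked against a pure base-R oracle.

## Worked example

```r
library(varwarehouse)

geography  <- generate_geography(24, seed = 2)
gene_models <- list(
  ensembl = generate_gene_model(30, 6, seed = 3, source = "ensembl"),
  refseq  = generate_gene_model(30, 6, seed = 3, source = "refseq"))
cl       <- generate_catalog(gene_models$ensembl, 800, seed = 4)
diseases <- generate_diseases(12, seed = 5)
samples  <- assign_samples(60, geography = geography, diseases = diseases,
                           disease_prevalence = 0.3, seed = 6)
fact <- simulate_cohort(cl$catalog, samples, gene_models, seed = 7)
nrow(fact)
#> [1] 4388
```

4 388 non-reference genotype calls for 60 samples × 800 variants — the
Hardy–Weinberg draw keeps most (sample, variant) pairs homozygous
reference, so they never materialize. Build the warehouse and ask for
per-region allele frequencies on the denormalized level:

```r
world <- list(fact = fact, samples = samples, geography = geography,
              gene_models = gene_models, diseases = diseases,
              predictions = cl$predictions, catalog = cl$catalog)
wh <- file.path(tempdir(), "wh_demo")
build_warehouse(world, wh)

session <- engine_open(sqlite_engine(), wh, level = "aggr_denorm")
q1a <- execute_query(session, "Q1A")
head(q1a[q1a$af > 0, ], 4)
#>   chrom   pos ref alt   region         af
#> 1     1 10039   A   T   Africa 0.13636364
#> 2     1 10039   A   T Americas 0.12500000
#> 3     1 10039   A   T     Asia 0.17857143
#> 4     1 10039   A   T   Europe 0.08695652
engine_close(session)
```

Each row is one variant in one continental region; `af` is
(n_het + 2·n_homalt) / (2·N_region), so the A>T site at 1:10039 is about
four times as frequent in the Asian subcohort as in the European one —
exactly the population-specific-polymorphism signal query Q1 exists to
surface. The in-memory oracle agrees:

```r
results_equal(q1a, oracle_query("Q1A", world = world))
#> [1] TRUE
```

Time a small benchmark (3 repetitions, raw vs denormalized, with oracle
cardinality verification):

```r
cfg <- list(repetitions = 3, levels = list("raw", "aggr_denorm"), verify = TRUE,
            queries = list(list(id = "Q1A", levels = list("raw", "aggr", "aggr_denorm")),
                           list(id = "Q6", levels = list("raw"))))
summarize_bench(run_bench(wh, cfg, world = world))
#>   query_id engine  format  codec       level n_ok mean_seconds min_seconds
#> 1      Q1A sqlite parquet snappy aggr_denorm    3   0.01266667       0.012
#> 2      Q1A sqlite parquet snappy         raw    3   0.01333333       0.013
#> 3       Q6 sqlite parquet snappy         raw    3   0.00600000       0.005
#>   max_seconds status
#> 1       0.014     ok
#> 2       0.014     ok
#> 3       0.007     ok
```

`plot_bench()` turns such summaries into grouped bar charts with min/max
error bars, one figure per query family.

## Command-line use

Thin wrappers over the same functions live in `inst/scripts/`:

```sh
Rscript inst/scripts/refgen.R   --n-genes 100 --n-variants 5000 --n-countries 181 \
                                --n-diseases 7569 --seed 1 --out refworld
Rscript inst/scripts/simulate.R --n-samples 200 --seed 1 --ref refworld --out warehouse
Rscript inst/scripts/build.R    --level cube --dir warehouse
Rscript inst/scripts/bench.R    --config bench.yaml --warehouse warehouse --out results
```

A `bench.yaml` lists `repetitions`, `engines`, `formats` (format + codec),
`levels`, `verify` and `queries` (id, applicable levels, params); the
timing CSV has one row per repetition with columns
`query_id, engine, format, codec, level, rep, wall_seconds, row_count, status`.

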
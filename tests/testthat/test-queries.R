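test_that("the suite declares 16 queries with their applicable levels", {
  specs <- query_specs()
  expect_length(specs, 16)
  for (q in c("Q1A", "Q1B", "Q2A", "Q2B", "Q3A", "Q3B", "Q4A", "Q4B")) {
    expect_setequal(unlist(specs[[q]]$levels), c("raw", "aggr", "aggr_denorm"))
  }
  for (q in paste0("Q", 5:12)) {
    expect_equal(unlist(specs[[q]]$levels), "raw")
  }
})

test_that("rendering substitutes parameters safely and validates pairs", {
  sql <- render_query("Q5", "raw", params = list(
    sample_id = 7, chrom = "12", start = 1000, end = 2000))
  expect_match(sql, "BETWEEN 1000 AND 2000")
  expect_match(sql, "sample_id = 7")
  expect_match(sql, "chrom = '12'")

  # unsupported (query, level) pair
  expect_error(render_query("Q5", "aggr", params = list(
    sample_id = 1, chrom = "1", start = 1, end = 2)), "not supported")
  # missing required parameter
  expect_error(render_query("Q3A", "raw"), "missing required parameter")
  # unknown parameter
  expect_error(render_query("Q6", "raw", params = list(bogus = 1)), "unknown parameter")
  # string parameters are quoted/escaped, not spliced
  inj <- render_query("Q10", "raw", params = list(chrom = "1'; DROP TABLE fact;--"))
  expect_match(inj, "'1''; DROP TABLE fact;--'", fixed = TRUE)
})

test_that("level variants of a template differ only in their source tables", {
  a <- render_query("Q1A", "aggr")
  d <- render_query("Q1A", "aggr_denorm")
  expect_false(identical(a, d))
  expect_match(a, "fact_agg_counts\\b")
  expect_match(d, "fact_agg_counts_dims")
  # the geography join disappears in the denormalized variant's counts CTE
  expect_match(a, "JOIN dim_geography g ON f.geo_fk")
  expect_no_match(d, "JOIN dim_geography g ON f.geo_fk")
  # source token selects the gene-model dimension
  rs <- render_query("Q11", "raw", params = list(source = "refseq"))
  expect_match(rs, "dim_genomic_position_refseq")
})

test_that("het/hom ratio oracle on a hand-built fixture gives 2.0", {
  fact <- data.frame(
    sample_id = 1L, chrom = "X", pos = 1:6 * 100L, ref = "A", alt = "G",
    genotype = c(rep("HET", 4), rep("HOM_ALT", 2)),
    dp = 30L, ad_alt = 15L, gl = NA_real_, geo_fk = 1L,
    region_fk_ens = 1L, region_fk_rs = 1L, disease_fk = NA_integer_,
    prediction_fk = 1L)
  world <- list(fact = fact)
  expect_equal(oracle_query("Q9", list(sample_id = 1L), world)$het_hom_ratio, 2.0)
  # zero alt homozygotes: undefined ratio surfaces as NA
  world$fact$genotype <- "HET"
  expect_true(is.na(oracle_query("Q9", list(sample_id = 1L), world)$het_hom_ratio))
})

test_that("saturated cohorts pin down Q6 and Q7 semantics", {
  geo <- generate_geography(4, seed = 1)
  gms <- list(ensembl = generate_gene_model(5, 4, seed = 2, source = "ensembl"),
              refseq = generate_gene_model(5, 4, seed = 2, source = "refseq"))
  cl <- generate_catalog(gms$ensembl, 30, af = af_hyperparams(fixed = 1), seed = 3)
  samples <- assign_samples(8, geography = geo, seed = 4)
  fact <- simulate_cohort(cl$catalog, samples, gms, seed = 5)
  world <- list(fact = fact, samples = samples, geography = geo,
                gene_models = gms, diseases = generate_diseases(0, 1),
                predictions = cl$predictions)
  dir <- withr::local_tempdir()
  build_warehouse(world, dir)
  session <- engine_open(sqlite_engine(), dir, level = "raw")
  withr::defer(engine_close(session))
  # every substitution occurrence count is a multiple of n_samples, and
  # counts sum to n_samples * n_variants
  q6 <- execute_query(session, "Q6")
  expect_equal(sum(q6$n), 8 * 30)
  expect_true(all(q6$n %% 8 == 0))
  expect_results_equal(q6, oracle_query("Q6", world = world))
  # distinct variants per chromosome sum to the catalog size
  q7 <- execute_query(session, "Q7")
  expect_equal(sum(q7$n), 30)
  expect_results_equal(q7, oracle_query("Q7", world = world))
})

test_that("substitution-type collapsing folds to the six pyrimidine classes", {
  q6 <- data.frame(substitution = c("C>G", "G>C", "A>T", "T>A", "G>A"),
                   n = c(1L, 2L, 4L, 8L, 16L))
  col <- collapse_substitutions(q6)
  expect_setequal(col$substitution, c("C>G", "T>A", "C>T"))
  expect_equal(col$n[col$substitution == "C>G"], 3L)
  expect_equal(col$n[col$substitution == "T>A"], 12L)
  expect_equal(col$n[col$substitution == "C>T"], 16L)
})

test_that("allele-frequency queries respect bounds and hierarchy consistency", {
  w <- small_world()
  q1a <- oracle_query("Q1A", world = w)
  q1b <- oracle_query("Q1B", world = w)
  expect_true(all(q1a$af >= 0 & q1a$af <= 1))
  expect_true(all(q1b$af >= 0 & q1b$af <= 1))
  # continent numerators are the integer sums of country numerators
  geo <- w$geography
  n_country <- table(geo$country[match(w$samples$geo_fk, geo$geo_id)])
  n_region <- table(geo$region[match(w$samples$geo_fk, geo$geo_id)])
  q1b$region <- geo$region[match(q1b$country, geo$country)]
  q1b$num <- round(q1b$af * 2 * as.numeric(n_country[q1b$country]))
  num_region <- rowsum(q1b$num,
                       paste(q1b$chrom, q1b$pos, q1b$ref, q1b$alt, q1b$region, sep = "\r"))
  q1a$num <- round(q1a$af * 2 * as.numeric(n_region[q1a$region]))
  key <- paste(q1a$chrom, q1a$pos, q1a$ref, q1a$alt, q1a$region, sep = "\r")
  expect_equal(q1a$num, as.vector(num_region[key, ]))
})

test_that("with the rarity and damaging filters off, Q2 counts all observed variants per transcript", {
  w <- small_world()
  loose <- oracle_query("Q2A", list(af_cutoff = 1.5, damaging_only = 0), world = w)
  # independent count: distinct observed variants per canonical transcript
  ens <- w$gene_models$ensembl
  can <- ens[ens$is_canonical, ]
  fact_v <- unique(w$fact[c("chrom", "pos", "ref", "alt")])
  counts <- integer(0)
  for (tx in split(can, can$transcript_id)) {
    hit <- vapply(seq_len(nrow(fact_v)), function(i) {
      any(tx$chrom == fact_v$chrom[i] & tx$start <= fact_v$pos[i] &
            tx$end >= fact_v$pos[i])
    }, logical(1))
    if (any(hit)) counts[tx$transcript_id[1]] <- sum(hit)
  }
  expect_setequal(loose$transcript_id, names(counts))
  expect_equal(loose$n_variants, unname(counts[loose$transcript_id]))
})

test_that("engine results equal the oracle on the small cohort at raw level", {
  w <- small_world()
  dir <- small_warehouse()
  session <- engine_open(sqlite_engine(), dir, level = "raw")
  withr::defer(engine_close(session))
  for (q in c("Q2B", "Q4A", "Q5", "Q8", "Q11", "Q12")) {
    params <- default_query_params(w, q)
    expect_results_equal(execute_query(session, q, params = params),
                         oracle_query(q, params = params, world = w),
                         info = q)
  }
})
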
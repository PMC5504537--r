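# shared fixtures, built in code and cached for the whole test session

.world_cache <- new.env(parent = emptyenv())

make_world <- function(n_samples, n_variants, n_countries = 24, n_genes = 30,
                       exons_per_gene_mean = 6, n_diseases = 10,
                       disease_prevalence = 0.3, af = af_hyperparams(),
                       damaging_fraction = 0.1, seed = 101) {
  geography <- generate_geography(n_countries, seed = seed + 1)
  gene_models <- list(
    ensembl = generate_gene_model(n_genes, exons_per_gene_mean, seed = seed + 2,
                                  source = "ensembl"),
    refseq = generate_gene_model(n_genes, exons_per_gene_mean, seed = seed + 2,
                                 source = "refseq"))
  cl <- generate_catalog(gene_models$ensembl, n_variants, af = af,
                         damaging_fraction = damaging_fraction, seed = seed + 3)
  diseases <- generate_diseases(n_diseases, seed = seed + 4)
  samples <- assign_samples(n_samples, geography = geography,
                            diseases = diseases,
                            disease_prevalence = disease_prevalence,
                            seed = seed + 5)
  fact <- simulate_cohort(cl$catalog, samples, gene_models, seed = seed + 6)
  list(fact = fact, samples = samples, geography = geography,
       gene_models = gene_models, diseases = diseases,
       predictions = cl$predictions, catalog = cl$catalog)
}

# the standard cohort fixture: 200 whole-exome samples x 5000 catalog
# variants over 181 countries, 100 genes, 25 diseases
fixture_world <- function() {
  if (is.null(.world_cache$world)) {
    .world_cache$world <- make_world(
      n_samples = 200, n_variants = 5000, n_countries = 181, n_genes = 100,
      exons_per_gene_mean = 8, n_diseases = 25, disease_prevalence = 0.3,
      seed = 7000)
  }
  .world_cache$world
}

# a small world for cheap structural tests
small_world <- function() {
  if (is.null(.world_cache$small)) {
    .world_cache$small <- make_world(n_samples = 40, n_variants = 500,
                                     seed = 4000, disease_prevalence = 0.4)
  }
  .world_cache$small
}

fixture_warehouse <- function() {
  if (is.null(.world_cache$wh_dir)) {
    dir <- file.path(tempdir(), "fixture_wh")
    build_warehouse(fixture_world(), dir)
    .world_cache$wh_dir <- dir
  }
  .world_cache$wh_dir
}

small_warehouse <- function() {
  if (is.null(.world_cache$small_wh_dir)) {
    dir <- file.path(tempdir(), "small_wh")
    build_warehouse(small_world(), dir)
    .world_cache$small_wh_dir <- dir
  }
  .world_cache$small_wh_dir
}

# an OMIM id actually carried by samples of a world (deterministic choice:
# the most frequent, ties broken by id)
fixture_omim <- function(world) {
  carried <- world$diseases$omim_id[match(world$samples$disease_fk,
                                          world$diseases$disease_id)]
  tab <- sort(table(carried), decreasing = TRUE)
  names(tab)[1]
}

default_query_params <- function(world, query_id) {
  switch(query_id,
         Q3A = , Q3B = list(omim_id = fixture_omim(world)),
         Q5 = list(sample_id = 1L, chrom = "1", start = 1L, end = 300000000L),
         Q8 = , Q9 = , Q12 = list(sample_id = 1L),
         Q10 = list(chrom = "1"),
         list())
}

# engine results for every query at every applicable level over the
# standard fixture warehouse (computed once, reused by several test files)
fixture_engine_results <- function() {
  if (is.null(.world_cache$engine_results)) {
    world <- fixture_world()
    dir <- fixture_warehouse()
    out <- list()
    for (lv in c("raw", "aggr", "aggr_denorm")) {
      session <- engine_open(sqlite_engine(), dir, level = lv)
      ids <- if (lv == "raw") query_ids() else
        c("Q1A", "Q1B", "Q2A", "Q2B", "Q3A", "Q3B", "Q4A", "Q4B")
      out[[lv]] <- lapply(
        stats::setNames(ids, ids),
        function(q) execute_query(session, q,
                                  params = default_query_params(world, q)))
      engine_close(session)
    }
    .world_cache$engine_results <- out
  }
  .world_cache$engine_results
}

expect_results_equal <- function(a, b, tol = 1e-9, info = NULL) {
  r <- results_equal(a, b, tol = tol)
  testthat::expect_true(isTRUE(r), info = paste(info, if (!isTRUE(r)) r))
}
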
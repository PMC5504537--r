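test_that("genotype probabilities follow the Hardy-Weinberg formula", {
  expect_equal(unname(genotype_probabilities(0)[1, ]), c(1, 0, 0))
  expect_equal(unname(genotype_probabilities(0.5)[1, ]), c(0.25, 0.5, 0.25))
  expect_equal(unname(genotype_probabilities(0.1)[1, ]), c(0.81, 0.18, 0.01))
  expect_error(genotype_probabilities(-0.1), "\\[0, 1\\]")
  expect_error(genotype_probabilities(1.2), "\\[0, 1\\]")

  af <- seq(0, 1, length.out = 101)
  p <- genotype_probabilities(af)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
})

test_that("genotype draws follow the allele frequency", {
  withr::with_seed(11, {
    expect_true(all(simulate_genotype(rep(0, 100)) == "HOM_REF"))
    expect_true(all(simulate_genotype(rep(1, 100)) == "HOM_ALT"))
    g <- simulate_genotype(rep(0.1, 100000))
    n_homalt <- sum(g == "HOM_ALT")
    # 4 sigma of Binomial(1e5, 0.01)
    expect_lt(abs(n_homalt - 1000), 4 * sqrt(100000 * 0.01 * 0.99))
  })
})

test_that("depth model keeps ad_alt within dp and honors genotype", {
  withr::with_seed(12, {
    d <- simulate_depth(rep(60, 20000), rep(c("HET", "HOM_ALT"), 10000))
    expect_true(all(d$ad_alt >= 0 & d$ad_alt <= d$dp))
    # a zero total depth forces zero allelic depth
    d0 <- simulate_depth(rep(0.01, 2000), "HET")
    expect_true(all(d0$ad_alt[d0$dp == 0] == 0))
    # error-free alt homozygotes carry only alt reads
    dh <- simulate_depth(rep(30, 1000), "HOM_ALT", eps = 0)
    expect_true(all(dh$ad_alt == dh$dp))
  })
  expect_error(simulate_depth(0, "HET"), "> 0")
  expect_error(simulate_depth(10, "HOM_REF"), "non-reference")
})

test_that("sample assignment is consistent with geography and weights by population", {
  geo <- generate_geography(4, seed = 1)
  s <- assign_samples(4, geography = geo, seed = 2)
  got <- geo$ethnic_group[match(s$geo_fk, geo$geo_id)]
  expect_identical(got, s$ethnic_group)

  # two EUR countries with a 10:1 population ratio
  geo2 <- data.frame(
    geo_id = 1:5,
    country = paste0("c", 1:5),
    subregion = c("s1", "s1", "s2", "s3", "s4"),
    region = c("Europe", "Europe", "Americas", "Asia", "Africa"),
    population = c(10000000L, 1000000L, 1L, 1L, 1L),
    ethnic_group = c("EUR", "EUR", "AMR", "EAS", "AFR"))
  s2 <- assign_samples(10000, ethnic_proportions = c(EUR = 1, AMR = 0, EAS = 0, AFR = 0),
                       geography = geo2, seed = 3)
  n1 <- sum(s2$geo_fk == 1)
  p <- 10 / 11
  expect_lt(abs(n1 - 10000 * p), 4 * sqrt(10000 * p * (1 - p)))

  expect_error(
    assign_samples(10, ethnic_proportions = c(EUR = 1, AMR = 0, EAS = 0, AFR = 0),
                   geography = geo2[geo2$ethnic_group != "EUR", ], seed = 1),
    "no countries")
})

test_that("degenerate allele frequencies produce empty and saturated fact streams", {
  geo <- generate_geography(4, seed = 1)
  gms <- list(ensembl = generate_gene_model(3, 3, seed = 2, source = "ensembl"),
              refseq = generate_gene_model(3, 3, seed = 2, source = "refseq"))
  samples <- assign_samples(10, geography = geo, seed = 3)

  zero <- generate_catalog(gms$ensembl, 20, af = af_hyperparams(fixed = 0), seed = 4)
  f0 <- simulate_cohort(zero$catalog, samples, gms, seed = 5)
  expect_equal(nrow(f0), 0)
  expect_named(f0, c("sample_id", "chrom", "pos", "ref", "alt", "genotype",
                     "dp", "ad_alt", "gl", "geo_fk", "region_fk_ens",
                     "region_fk_rs", "disease_fk", "prediction_fk"))

  one <- generate_catalog(gms$ensembl, 20, af = af_hyperparams(fixed = 1), seed = 4)
  f1 <- simulate_cohort(one$catalog, samples, gms, seed = 5)
  expect_equal(nrow(f1), 10 * 20)
  expect_true(all(f1$genotype == "HOM_ALT"))
})

test_that("emitted fact row count matches the analytic expectation", {
  w <- fixture_world()
  afm <- as.matrix(w$catalog[paste0("af_", ethnic_groups())])
  colnames(afm) <- ethnic_groups()
  p0 <- 1 - 2 * afm + afm^2
  n_g <- table(w$samples$ethnic_group)[ethnic_groups()]
  mu <- sum(t(1 - p0) * as.numeric(n_g))
  v <- sum(t(p0 * (1 - p0)) * as.numeric(n_g))
  expect_lt(abs(nrow(w$fact) - mu), 4 * sqrt(v))
})

test_that("cohort simulation is deterministic and ordered", {
  w <- small_world()
  again <- simulate_cohort(w$catalog, w$samples, w$gene_models, seed = 4006)
  expect_identical(w$fact, again)
  o <- order(w$fact$sample_id, match(w$fact$chrom, chromosomes()), w$fact$pos)
  expect_identical(o, seq_len(nrow(w$fact)))
})

test_that("fact records resolve regions, store only non-reference calls, keep ad within dp", {
  w <- small_world()
  f <- w$fact
  expect_true(all(f$genotype %in% c("HET", "HOM_ALT")))
  expect_true(all(f$ad_alt >= 0 & f$ad_alt <= f$dp))
  ens <- w$gene_models$ensembl
  i <- match(f$region_fk_ens, ens$region_id)
  expect_true(all(ens$is_merged[i]))
  expect_true(all(ens$chrom[i] == f$chrom & ens$start[i] <= f$pos & ens$end[i] >= f$pos))
})

test_that("per-group empirical allele frequencies recover catalog frequencies", {
  w <- small_world()
  afm <- as.matrix(w$catalog[paste0("af_", ethnic_groups())])
  n_g <- table(w$samples$ethnic_group)[ethnic_groups()]
  vk <- paste(w$catalog$chrom, w$catalog$pos)
  grp <- w$samples$ethnic_group[match(w$fact$sample_id, w$samples$sample_id)]
  alle <- (w$fact$genotype == "HET") + 2 * (w$fact$genotype == "HOM_ALT")
  agg <- rowsum(alle, paste(paste(w$fact$chrom, w$fact$pos), grp))
  emp <- sapply(ethnic_groups(), function(g) {
    hit <- match(paste(vk, g), rownames(agg))
    ifelse(is.na(hit), 0, agg[hit, 1]) / (2 * as.numeric(n_g[[g]]))
  })
  fit <- stats::lm(as.vector(emp) ~ as.vector(afm))
  expect_lt(abs(unname(stats::coef(fit)[2]) - 1), 0.05)
})
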
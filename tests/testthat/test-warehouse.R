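sorted_multiset <- function(df) {
  df <- as.data.frame(df)
  df <- df[do.call(order, c(unname(df), list(method = "radix"))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

test_that("empty fact stream yields an empty table with the full schema", {
  w <- small_world()
  dir <- withr::local_tempdir()
  wh_create(dir)
  build_fact(w$fact[0, ], dir)
  back <- wh_read(dir, "fact")
  expect_equal(nrow(back), 0)
  expect_named(back, names(w$fact))
})

test_that("columnar fact storage conserves rows and round-trips as a multiset", {
  w <- small_world()
  dir <- withr::local_tempdir()
  wh_create(dir)
  slice <- w$fact[1:1000, ]
  res <- build_fact(slice, dir)
  expect_equal(res$n_written, 1000)
  back <- wh_read(dir, "fact")
  expect_equal(nrow(back), 1000)
  expect_equal(sorted_multiset(back), sorted_multiset(slice))
})

test_that("gzip and uncompressed parquet, and feather, round-trip identically", {
  w <- small_world()
  slice <- w$fact[1:200, ]
  for (v in list(c("parquet", "gzip"), c("parquet", "none"), c("feather", "snappy"))) {
    dir <- withr::local_tempdir()
    wh_create(dir)
    wh_write(dir, "t", slice, format = v[1], codec = v[2])
    back <- wh_read(dir, "t", format = v[1])
    expect_equal(sorted_multiset(back), sorted_multiset(slice), info = v[1])
  }
})

test_that("records with unresolvable foreign keys are rejected and counted", {
  w <- small_world()
  dir <- withr::local_tempdir()
  wh_create(dir)
  bad <- w$fact[1:10, ]
  bad$geo_fk[3] <- 999999L
  dims <- w[c("geography", "gene_models", "diseases", "predictions")]
  expect_message(res <- build_fact(bad, dir, dims = dims), "rejected")
  expect_equal(res$n_rejected, 1)
  expect_equal(nrow(wh_read(dir, "fact")), 9)
})

test_that("aggregated counts match a brute-force group-by and conserve totals", {
  w <- small_world()
  agg <- build_agg_counts(w$fact)
  # single-record sanity
  one <- w$fact[w$fact$genotype == "HET", ][1, ]
  a1 <- build_agg_counts(one)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$n_het, 1)
  expect_equal(a1$n_homalt, 0)
  # conservation of record count
  expect_equal(sum(agg$n_het + agg$n_homalt), nrow(w$fact))
  # surrogate key
  expect_equal(anyDuplicated(agg$agg_id), 0)
  # independent group-by oracle via tapply on pasted keys
  key <- paste(w$fact$chrom, w$fact$pos, w$fact$ref, w$fact$alt,
               w$fact$geo_fk, w$fact$disease_fk, sep = "|")
  het <- tapply(w$fact$genotype == "HET", key, sum)
  hom <- tapply(w$fact$genotype == "HOM_ALT", key, sum)
  akey <- paste(agg$chrom, agg$pos, agg$ref, agg$alt, agg$geo_fk,
                agg$disease_fk, sep = "|")
  expect_setequal(akey, names(het))
  expect_equal(agg$n_het, as.vector(het[akey]))
  expect_equal(agg$n_homalt, as.vector(hom[akey]))
  # the key combination is unique
  expect_equal(anyDuplicated(akey), 0)
})

test_that("depth histogram conserves records and depth mass", {
  w <- small_world()
  dp_hist <- build_agg_depth(w$fact)
  expect_equal(sum(dp_hist$n), nrow(w$fact))
  expect_equal(sum(dp_hist$dp * dp_hist$n), sum(w$fact$dp))
})

test_that("denormalization is a 1:1 reversible join carrying dimension literals", {
  w <- small_world()
  dims <- w[c("geography", "gene_models", "diseases", "predictions")]
  agg <- build_agg_counts(w$fact)
  wide <- build_agg_denorm(agg, dims)
  expect_equal(nrow(wide), nrow(agg))
  # spot-check geography literals
  i <- which(!is.na(agg$disease_fk))[1]
  g <- w$geography[w$geography$geo_id == agg$geo_fk[i], ]
  expect_equal(wide$country[i], g$country)
  expect_equal(wide$region[i], g$region)
  expect_equal(wide$omim_id[i],
               w$diseases$omim_id[w$diseases$disease_id == agg$disease_fk[i]])
  # inverse projection: re-keying the attributes reproduces level 2
  rekey <- data.frame(
    chrom = wide$chrom, pos = wide$pos, ref = wide$ref, alt = wide$alt,
    geo_fk = w$geography$geo_id[match(wide$country, w$geography$country)],
    disease_fk = w$diseases$disease_id[match(wide$omim_id, w$diseases$omim_id)],
    region_fk_ens = w$gene_models$ensembl$region_id[
      match(paste(wide$transcript_id_ens, wide$exon_number_ens),
            paste(w$gene_models$ensembl$transcript_id,
                  w$gene_models$ensembl$exon_number))],
    region_fk_rs = w$gene_models$refseq$region_id[
      match(paste(wide$transcript_id_rs, wide$exon_number_rs),
            paste(w$gene_models$refseq$transcript_id,
                  w$gene_models$refseq$exon_number))],
    n_het = wide$n_het, n_homalt = wide$n_homalt)
  lvl2 <- agg[names(rekey)]
  expect_equal(sorted_multiset(rekey), sorted_multiset(lvl2))
  # dangling FK fails fast
  broken <- agg
  broken$geo_fk[1] <- 999999L
  expect_error(build_agg_denorm(broken, dims), "dangling")
})

test_that("allele counts are conserved across all storage levels", {
  w <- small_world()
  dims <- w[c("geography", "gene_models", "diseases", "predictions")]
  alleles_raw <- sum((w$fact$genotype == "HET") + 2 * (w$fact$genotype == "HOM_ALT"))
  agg <- build_agg_counts(w$fact)
  wide <- build_agg_denorm(agg, dims)
  expect_identical(sum(agg$n_het + 2 * agg$n_homalt), alleles_raw)
  expect_identical(sum(wide$n_het + 2 * wide$n_homalt), alleles_raw)
})

test_that("warehouse catalog registers every table of every level", {
  dir <- small_warehouse()
  tabs <- wh_tables(dir)
  expect_setequal(
    tabs$name,
    c("dim_geography", "dim_genomic_position_ensembl",
      "dim_genomic_position_refseq", "dim_disease", "dim_variant_predictions",
      "samples", "fact", "fact_agg_counts", "fact_agg_depth",
      "fact_agg_counts_dims", "fact_agg_depth_dims"))
  expect_error(wh_read(dir, "nope"), "not registered")
})
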
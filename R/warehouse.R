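#' Create (or reset) a warehouse directory
#'
#' A warehouse is a directory of columnar tables plus a lightweight JSON
#' catalog (`catalog.json`) mapping table name -> path, format, codec and
#' storage level; the catalog stands in for a metastore.
#'
#' @param dir Directory path.
#' @return The directory path, invisibly.
#' @export
wh_create <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(stats::setNames(list(), character(0)),
                       file.path(dir, "catalog.json"), auto_unbox = TRUE)
  invisible(dir)
}

wh_catalog <- function(dir) {
  path <- file.path(dir, "catalog.json")
  if (!file.exists(path)) stop("no catalog.json in ", dir, "; call wh_create() first")
  jsonlite::read_json(path)
}

wh_table_key <- function(name, format, codec) paste(name, format, codec, sep = "::")

#' Write a table into the warehouse
#'
#' @param dir Warehouse directory.
#' @param name Table name (e.g. `"dim_geography"`).
#' @param df Data frame.
#' @param format `"parquet"` (the mandatory columnar writer) or `"feather"`
#'   (a second columnar format behind the same interface, for
#'   format-comparison timing studies).
#' @param codec Compression codec: `"snappy"`, `"gzip"` or `"none"`.
#' @param level Storage level label the table belongs to (`"dim"`, `"raw"`,
#'   `"aggr"`, `"aggr_denorm"`).
#' @param partition_by Optional single column name; the table is written as
#'   one file per value (used for the fact table, partitioned by chromosome).
#' @return The table name, invisibly.
#' @export
wh_write <- function(dir, name, df, format = "parquet", codec = "snappy",
                     level = "dim", partition_by = NULL) {
  cat <- wh_catalog(dir)
  codec_arrow <- switch(codec, none = "uncompressed", snappy = "snappy",
                        gzip = "gzip", stop("unknown codec: ", codec))
  rel <- file.path("tables", paste(name, format, codec, sep = "_"))
  full <- file.path(dir, rel)
  unlink(full, recursive = TRUE)
  dir.create(full, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(d, path) {
    if (format == "parquet") {
      arrow::write_parquet(d, path, compression = codec_arrow)
    } else if (format == "feather") {
      arrow::write_feather(d, path, compression = switch(
        codec, none = "uncompressed", "zstd"))
    } else stop("unknown format: ", format)
  }
  if (is.null(partition_by)) {
    write_one(df, file.path(full, paste0("part-0.", format)))
    parts <- NULL
  } else {
    vals <- unique(df[[partition_by]])
    for (v in vals) {
      write_one(df[df[[partition_by]] == v, , drop = FALSE],
                file.path(full, paste0(partition_by, "=", v, ".", format)))
    }
    parts <- as.character(vals)
  }
  cat[[wh_table_key(name, format, codec)]] <- list(
    name = name, path = rel, format = format, codec = codec, level = level,
    partition_by = partition_by, n_rows = nrow(df),
    schema = stats::setNames(as.list(vapply(df, function(x) class(x)[1], character(1))),
                             names(df))
  )
  jsonlite::write_json(cat, file.path(dir, "catalog.json"), auto_unbox = TRUE)
  invisible(name)
}

#' Read a table back from the warehouse
#'
#' @param dir Warehouse directory.
#' @param name Table name.
#' @param format,codec Physical variant to read; defaults pick the first
#'   registered variant of `name`.
#' @return A data.frame.
#' @export
wh_read <- function(dir, name, format = NULL, codec = NULL) {
  cat <- wh_catalog(dir)
  hits <- Filter(function(e) e$name == name &&
                   (is.null(format) || e$format == format) &&
                   (is.null(codec) || e$codec == codec), cat)
  if (length(hits) == 0L) stop("table not registered: ", name)
  e <- hits[[1]]
  files <- sort(list.files(file.path(dir, e$path), full.names = TRUE))
  reader <- if (e$format == "parquet") arrow::read_parquet else arrow::read_feather
  parts <- lapply(files, function(f) as.data.frame(reader(f)))
  df <- do.call(rbind, parts)
  # restore logical columns (parquet round-trips them; be defensive for orc)
  for (nm in names(e$schema)) {
    if (identical(e$schema[[nm]], "logical") && !is.logical(df[[nm]])) {
      df[[nm]] <- as.logical(df[[nm]])
    }
    if (identical(e$schema[[nm]], "integer") && !is.integer(df[[nm]])) {
      df[[nm]] <- as.integer(df[[nm]])
    }
  }
  rownames(df) <- NULL
  df
}

#' List registered warehouse tables
#'
#' @param dir Warehouse directory.
#' @return A data.frame with one row per registered (name, format, codec).
#' @export
wh_tables <- function(dir) {
  cat <- wh_catalog(dir)
  if (length(cat) == 0L) {
    return(data.frame(name = character(0), format = character(0),
                      codec = character(0), level = character(0),
                      n_rows = integer(0)))
  }
  do.call(rbind, lapply(unname(cat), function(e) {
    data.frame(name = e$name, format = e$format, codec = e$codec,
               level = e$level, n_rows = e$n_rows, stringsAsFactors = FALSE)
  }))
}

fact_schema_cols <- function() {
  c("sample_id", "chrom", "pos", "ref", "alt", "genotype", "dp", "ad_alt",
    "gl", "geo_fk", "region_fk_ens", "region_fk_rs", "disease_fk",
    "prediction_fk")
}

#' Store the raw fact table (storage level 1)
#'
#' Writes the genotype-call fact stream as a columnar table partitioned by
#' chromosome and sorted by (chrom, ref, alt, sample_id) within partitions
#' (low-cardinality leading sort keys aid columnar compression). Records
#' whose foreign keys do not resolve against the supplied dimensions are
#' rejected and counted.
#'
#' @param fact Fact data.frame from [simulate_cohort()].
#' @param dir Warehouse directory.
#' @param dims Optional named list of dimension tables (`geography`,
#'   `gene_models`, `diseases`, `predictions`) used to validate foreign keys.
#' @param format,codec Physical storage options.
#' @return Invisibly, a list with `n_written` and `n_rejected`.
#' @export
build_fact <- function(fact, dir, dims = NULL, format = "parquet",
                       codec = "snappy") {
  stopifnot(all(fact_schema_cols() %in% names(fact)))
  fact <- fact[fact_schema_cols()]
  n_in <- nrow(fact)
  if (!is.null(dims) && n_in > 0L) {
    ok <- fact$geo_fk %in% dims$geography$geo_id &
      fact$region_fk_ens %in% dims$gene_models$ensembl$region_id &
      fact$region_fk_rs %in% dims$gene_models$refseq$region_id &
      fact$prediction_fk %in% dims$predictions$prediction_fk &
      (is.na(fact$disease_fk) | fact$disease_fk %in% dims$diseases$disease_id)
    if (any(!ok)) {
      message(sum(!ok), " fact record(s) rejected: unresolvable foreign keys")
      fact <- fact[ok, , drop = FALSE]
    }
  }
  if (nrow(fact) > 0L) {
    fact <- fact[order(chrom_rank(fact$chrom), fact$ref, fact$alt, fact$sample_id), ]
  }
  wh_write(dir, "fact", fact, format = format, codec = codec, level = "raw",
           partition_by = if (nrow(fact) > 0L) "chrom" else NULL)
  invisible(list(n_written = nrow(fact), n_rejected = n_in - nrow(fact)))
}

agg_key_cols <- function() {
  c("chrom", "pos", "ref", "alt", "geo_fk", "disease_fk",
    "region_fk_ens", "region_fk_rs", "prediction_fk")
}

#' Build the aggregated-counts table (storage level 2)
#'
#' One row per (variant, country, disease) with heterozygote and
#' alt-homozygote call counts; all dimension foreign keys are carried. An
#' artificial surrogate primary key (`agg_id`) is added.
#'
#' @param fact Raw fact data.frame.
#' @return A data.frame of aggregated counts.
#' @export
build_agg_counts <- function(fact) {
  keys <- agg_key_cols()
  out <- fact |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_het = sum(genotype == "HET"),
      n_homalt = sum(genotype == "HOM_ALT"),
      .groups = "drop"
    ) |>
    as.data.frame()
  out <- out[do.call(order, c(unname(out[keys]), list(method = "radix"))), ]
  rownames(out) <- NULL
  cbind(agg_id = seq_len(nrow(out)), out)
}

#' Build the aggregated depth-histogram companion table (storage level 2)
#'
#' Depth-of-coverage quantile queries cannot be recomputed from genotype
#' counts alone, so the aggregated level also stores the exact depth
#' distribution: one row per (variant, country, disease, dp) with the number
#' of fact records at that depth.
#'
#' @param fact Raw fact data.frame.
#' @return A data.frame with the aggregation keys plus `dp` and `n`.
#' @export
build_agg_depth <- function(fact) {
  keys <- c(agg_key_cols(), "dp")
  out <- fact |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    as.data.frame()
  out <- out[do.call(order, c(unname(out[keys]), list(method = "radix"))), ]
  rownames(out) <- NULL
  cbind(agg_id = seq_len(nrow(out)), out)
}

# join a FK column against a dimension, failing fast on dangling keys;
# returns the dimension rows aligned to `fk` (NA fk -> NA attributes)
join_dim <- function(fk, dim, key_col, what) {
  idx <- match(fk, dim[[key_col]])
  bad <- !is.na(fk) & is.na(idx)
  if (any(bad)) {
    stop("dangling ", what, " foreign key(s): e.g. ", fk[which(bad)[1]])
  }
  dim[idx, , drop = FALSE]
}

#' Denormalize an aggregated table (storage level 3)
#'
#' Replaces every foreign key of a level-2 table by the corresponding
#' dimension attributes (geography hierarchy, gene/transcript/exon of the
#' merged-transcript assignment for both annotation sources, disease OMIM id
#' and name, damaging flag), yielding one wide pre-joined table. Dangling
#' foreign keys are an error.
#'
#' @param level2 Output of [build_agg_counts()] or [build_agg_depth()].
#' @param dims Named list with `geography`, `gene_models` (list with
#'   `ensembl`, `refseq`), `diseases`, `predictions`.
#' @return A wide data.frame without foreign-key columns.
#' @export
build_agg_denorm <- function(level2, dims) {
  geo <- join_dim(level2$geo_fk, dims$geography, "geo_id", "geography")
  dis <- join_dim(level2$disease_fk, dims$diseases, "disease_id", "disease")
  ens <- join_dim(level2$region_fk_ens, dims$gene_models$ensembl, "region_id",
                  "ensembl region")
  rs <- join_dim(level2$region_fk_rs, dims$gene_models$refseq, "region_id",
                 "refseq region")
  prd <- join_dim(level2$prediction_fk, dims$predictions, "prediction_fk",
                  "prediction")
  out <- data.frame(
    agg_id = level2$agg_id,
    chrom = level2$chrom, pos = level2$pos, ref = level2$ref, alt = level2$alt,
    country = geo$country, subregion = geo$subregion, region = geo$region,
    ethnic_group = geo$ethnic_group,
    omim_id = dis$omim_id, disease_name = dis$name,
    gene_symbol_ens = ens$gene_symbol, transcript_id_ens = ens$transcript_id,
    exon_number_ens = ens$exon_number, exon_start_ens = ens$start,
    exon_end_ens = ens$end,
    gene_symbol_rs = rs$gene_symbol, transcript_id_rs = rs$transcript_id,
    exon_number_rs = rs$exon_number, exon_start_rs = rs$start,
    exon_end_rs = rs$end,
    fathmm_damaging = prd$fathmm_damaging,
    stringsAsFactors = FALSE
  )
  measure_cols <- intersect(c("n_het", "n_homalt", "dp", "n"), names(level2))
  for (m in measure_cols) out[[m]] <- level2[[m]]
  rownames(out) <- NULL
  out
}

#' Build every storage level of a warehouse from a simulated world
#'
#' Convenience orchestrator: registers all dimension tables and the sample
#' registry, then the raw fact table (level 1), the aggregated counts and
#' depth histogram (level 2) and their denormalized forms (level 3), for
#' each requested (format, codec) combination.
#'
#' @param world A list with `fact`, `samples`, `geography`, `gene_models`,
#'   `diseases`, `predictions` (see [simulate_cohort()] and the `generate_*`
#'   functions).
#' @param dir Warehouse directory (created/reset).
#' @param formats List of `list(format=, codec=)` physical variants.
#' @return The warehouse directory, invisibly.
#' @export
build_warehouse <- function(world, dir,
                            formats = list(list(format = "parquet", codec = "snappy"))) {
  wh_create(dir)
  dims <- world[c("geography", "gene_models", "diseases", "predictions")]
  agg <- build_agg_counts(world$fact)
  agg_dp <- build_agg_depth(world$fact)
  denorm <- build_agg_denorm(agg, dims)
  denorm_dp <- build_agg_denorm(agg_dp, dims)
  for (f in formats) {
    fmt <- f$format %||% "parquet"
    cdc <- f$codec %||% "snappy"
    wh_write(dir, "dim_geography", world$geography, fmt, cdc, level = "dim")
    wh_write(dir, "dim_genomic_position_ensembl", world$gene_models$ensembl,
             fmt, cdc, level = "dim")
    wh_write(dir, "dim_genomic_position_refseq", world$gene_models$refseq,
             fmt, cdc, level = "dim")
    wh_write(dir, "dim_disease", world$diseases, fmt, cdc, level = "dim")
    wh_write(dir, "dim_variant_predictions", world$predictions, fmt, cdc,
             level = "dim")
    wh_write(dir, "samples", world$samples, fmt, cdc, level = "dim")
    build_fact(world$fact, dir, dims = dims, format = fmt, codec = cdc)
    wh_write(dir, "fact_agg_counts", agg, fmt, cdc, level = "aggr")
    wh_write(dir, "fact_agg_depth", agg_dp, fmt, cdc, level = "aggr")
    wh_write(dir, "fact_agg_counts_dims", denorm, fmt, cdc, level = "aggr_denorm")
    wh_write(dir, "fact_agg_depth_dims", denorm_dp, fmt, cdc, level = "aggr_denorm")
  }
  invisible(dir)
}
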
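# ---- pure in-memory reference implementations of the query suite ----
#
# These oracles compute each query's definition directly with base-R loops
# and maps over the in-memory world (fact + dimensions + sample registry),
# never through SQL, so they serve as an independent correctness reference
# for the engine route.

SEP <- "\r"

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = SEP)

# per-variant alt-allele count contributed by each fact record
alt_alleles <- function(genotype) {
  (genotype == "HET") + 2L * (genotype == "HOM_ALT")
}

oracle_q1 <- function(world, geo_col) {
  fact <- world$fact
  geo <- world$geography
  samp_attr <- geo[[geo_col]][match(world$samples$geo_fk, geo$geo_id)]
  n_by <- table(samp_attr)
  groups <- sort(names(n_by))
  vkey <- variant_key(fact)
  variants <- fact[!duplicated(vkey), c("chrom", "pos", "ref", "alt")]
  vkeys <- vkey[!duplicated(vkey)]
  fact_attr <- geo[[geo_col]][match(fact$geo_fk, geo$geo_id)]
  num <- rowsum(alt_alleles(fact$genotype), paste(vkey, fact_attr, sep = SEP))
  grid_v <- rep(seq_len(nrow(variants)), times = length(groups))
  grid_g <- rep(groups, each = nrow(variants))
  lookup <- num[match(paste(vkeys[grid_v], grid_g, sep = SEP), rownames(num)), 1]
  lookup[is.na(lookup)] <- 0
  out <- variants[grid_v, , drop = FALSE]
  out[[geo_col]] <- grid_g
  out$af <- lookup / (2 * as.numeric(n_by[grid_g]))
  rownames(out) <- NULL
  out
}

# scan one gene-model slice (canonical transcripts or merged exons) against
# per-variant/record positions; `value` rows are aggregated per group key
interval_scan <- function(dim_rows, chrom, pos) {
  hits <- vector("list", nrow(dim_rows))
  by_chrom <- split(seq_along(pos), chrom)
  for (i in seq_len(nrow(dim_rows))) {
    idx <- by_chrom[[dim_rows$chrom[i]]]
    if (is.null(idx)) next
    p <- pos[idx]
    hits[[i]] <- idx[p >= dim_rows$start[i] & p <= dim_rows$end[i]]
  }
  hits
}

gp_slice <- function(world, source, sub) {
  gm <- world$gene_models[[source]]
  if (sub == "A") gm[gm$is_canonical, , drop = FALSE]
  else gm[gm$is_merged, , drop = FALSE]
}

gp_group_cols <- function(dim_rows, sub) {
  if (sub == "A") {
    data.frame(transcript_id = dim_rows$transcript_id, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = dim_rows$transcript_id,
               exon_number = dim_rows$exon_number,
               exon_start = dim_rows$start, exon_end = dim_rows$end,
               stringsAsFactors = FALSE)
  }
}

# aggregate per-dim-row hit statistics onto the A/B group key
gp_aggregate <- function(dim_rows, sub, stats_df) {
  keys <- gp_group_cols(dim_rows, sub)
  kstr <- do.call(paste, c(unname(keys), list(sep = SEP)))
  keep <- !vapply(stats_df$empty, isTRUE, logical(1))
  if (!any(keep)) {
    return(cbind(keys[0, , drop = FALSE], stats_df$value[0, , drop = FALSE]))
  }
  first <- tapply(seq_len(nrow(keys))[keep], kstr[keep], `[`, 1)
  sums <- rowsum(stats_df$value[keep, , drop = FALSE], kstr[keep])
  out <- cbind(keys[first[rownames(sums)], , drop = FALSE],
               as.data.frame(sums))
  rownames(out) <- NULL
  out
}

oracle_q2 <- function(world, sub, params) {
  fact <- world$fact
  n_total <- nrow(world$samples)
  vkey <- variant_key(fact)
  af_num <- rowsum(alt_alleles(fact$genotype), vkey)
  first <- !duplicated(vkey)
  variants <- fact[first, c("chrom", "pos", "ref", "alt", "prediction_fk")]
  variants$af <- af_num[match(vkey[first], rownames(af_num)), 1] / (2 * n_total)
  dmg <- world$predictions$fathmm_damaging[
    match(variants$prediction_fk, world$predictions$prediction_fk)]
  keep <- variants$af < params$af_cutoff &
    (params$damaging_only == 0 | dmg)
  variants <- variants[keep, , drop = FALSE]
  dim_rows <- gp_slice(world, params$source, sub)
  hits <- interval_scan(dim_rows, variants$chrom, variants$pos)
  value <- do.call(rbind, lapply(hits, function(h) {
    c(n_variants = length(h), cum_af = sum(variants$af[h]))
  }))
  res <- gp_aggregate(dim_rows, sub,
                      list(value = value,
                           empty = lapply(hits, function(h) length(h) == 0L)))
  res <- res[res$n_variants > 0, , drop = FALSE]
  res$n_variants <- as.integer(res$n_variants)
  rownames(res) <- NULL
  res
}

oracle_q3 <- function(world, sub, params) {
  did <- world$diseases$disease_id[world$diseases$omim_id == params$omim_id]
  fact <- world$fact
  fact <- fact[!is.na(fact$disease_fk) & fact$disease_fk %in% did, , drop = FALSE]
  dim_rows <- gp_slice(world, params$source, sub)
  hits <- interval_scan(dim_rows, fact$chrom, fact$pos)
  value <- matrix(vapply(hits, length, integer(1)), ncol = 1,
                  dimnames = list(NULL, "n_records"))
  res <- gp_aggregate(dim_rows, sub,
                      list(value = value,
                           empty = lapply(hits, function(h) length(h) == 0L)))
  res <- res[res$n_records > 0, , drop = FALSE]
  res$n_records <- as.integer(res$n_records)
  rownames(res) <- NULL
  res
}

oracle_q4 <- function(world, sub, params) {
  fact <- world$fact
  dim_rows <- gp_slice(world, params$source, sub)
  hits <- interval_scan(dim_rows, fact$chrom, fact$pos)
  keys <- gp_group_cols(dim_rows, sub)
  kstr <- do.call(paste, c(unname(keys), list(sep = SEP)))
  groups <- split(seq_len(nrow(dim_rows)), kstr)
  rows <- lapply(groups, function(ri) {
    dp <- fact$dp[unlist(hits[ri], use.names = FALSE)]
    if (length(dp) == 0L) return(NULL)
    q <- stats::quantile(dp, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    cbind(keys[ri[1], , drop = FALSE],
          data.frame(min_dp = q[1], q25_dp = q[2], median_dp = q[3],
                     q75_dp = q[4], max_dp = q[5]))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- cbind(keys[0, , drop = FALSE],
                                 data.frame(min_dp = numeric(0), q25_dp = numeric(0),
                                            median_dp = numeric(0), q75_dp = numeric(0),
                                            max_dp = numeric(0)))
  rownames(out) <- NULL
  out
}

#' Compute a query's reference answer directly in memory
#'
#' The independent correctness reference for [execute_query()]: each query's
#' definition is evaluated with plain base-R operations over the in-memory
#' world, without SQL. Results are canonically ordered.
#'
#' @param query_id Query id (see [query_ids()]).
#' @param params Named list of query parameters (defaults from the YAML
#'   descriptors apply).
#' @param world A list with `fact`, `samples`, `geography`, `gene_models`,
#'   `diseases`, `predictions`.
#' @return A canonically ordered data.frame with the same columns as the
#'   engine result.
#' @export
oracle_query <- function(query_id, params = list(), world) {
  spec <- query_spec(query_id)
  params <- merge_params(spec, params)
  fact <- world$fact
  out <- switch(
    query_id,
    Q1A = oracle_q1(world, "region"),
    Q1B = oracle_q1(world, "country"),
    Q2A = oracle_q2(world, "A", params),
    Q2B = oracle_q2(world, "B", params),
    Q3A = oracle_q3(world, "A", params),
    Q3B = oracle_q3(world, "B", params),
    Q4A = oracle_q4(world, "A", params),
    Q4B = oracle_q4(world, "B", params),
    Q5 = {
      sel <- fact$sample_id == params$sample_id & fact$chrom == params$chrom &
        fact$pos >= params$start & fact$pos <= params$end
      fact[sel, c("chrom", "pos", "ref", "alt", "genotype", "dp", "ad_alt")]
    },
    Q6 = {
      sub <- paste0(fact$ref, ">", fact$alt)
      tab <- table(sub)
      data.frame(substitution = names(tab), n = as.integer(tab),
                 stringsAsFactors = FALSE)
    },
    Q7 = {
      vk <- paste(fact$pos, fact$ref, fact$alt, sep = SEP)
      uniq <- !duplicated(paste(fact$chrom, vk, sep = SEP))
      tab <- table(fact$chrom[uniq])
      data.frame(chrom = names(tab), n = as.integer(tab),
                 stringsAsFactors = FALSE)
    },
    Q8 = {
      sel <- fact$sample_id == params$sample_id & fact$dp > 0 &
        fact$ad_alt / fact$dp > 0.9
      data.frame(n = sum(sel))
    },
    Q9 = {
      sel <- fact$sample_id == params$sample_id & fact$chrom == "X"
      n_het <- sum(fact$genotype[sel] == "HET")
      n_hom <- sum(fact$genotype[sel] == "HOM_ALT")
      data.frame(het_hom_ratio = if (n_hom == 0) NA_real_ else n_het / n_hom)
    },
    Q10 = {
      sel <- fact$chrom == params$chrom
      tab <- table(fact$sample_id[sel])
      data.frame(sample_id = as.integer(names(tab)), n = as.integer(tab))
    },
    Q11 = {
      dim_rows <- gp_slice(world, params$source, "B")
      hits <- interval_scan(dim_rows, fact$chrom, fact$pos)
      pairs <- unique(data.frame(
        sample_id = fact$sample_id[unlist(hits, use.names = FALSE)],
        gene_symbol = rep(dim_rows$gene_symbol,
                          times = vapply(hits, length, integer(1)))
      ))
      tab <- table(pairs$sample_id)
      data.frame(sample_id = as.integer(names(tab)), n_genes = as.integer(tab))
    },
    Q12 = {
      sel <- fact$sample_id == params$sample_id
      tab <- table(fact$chrom[sel])
      data.frame(chrom = names(tab), n = as.integer(tab),
                 stringsAsFactors = FALSE)
    },
    stop("unknown query id: ", query_id)
  )
  canonicalize_result(out)
}

#' Collapse substitution types to strand-equivalence classes
#'
#' Optionally folds the 12 ref>alt substitution types onto the 6
#' pyrimidine-anchored classes (e.g. `G>A` is reported as `C>T`). Applies to
#' the output of query Q6; the default convention of the suite is no
#' collapsing.
#'
#' @param q6_result Data frame with columns `substitution`, `n`.
#' @return Data frame with collapsed substitution classes.
#' @export
collapse_substitutions <- function(q6_result) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  parts <- strsplit(q6_result$substitution, ">", fixed = TRUE)
  ref <- vapply(parts, `[`, character(1), 1)
  alt <- vapply(parts, `[`, character(1), 2)
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, comp[ref], ref)
  alt2 <- ifelse(flip, comp[alt], alt)
  agg <- rowsum(q6_result$n, paste0(ref2, ">", alt2))
  data.frame(substitution = rownames(agg), n = as.integer(agg[, 1]),
             stringsAsFactors = FALSE, row.names = NULL)
}
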
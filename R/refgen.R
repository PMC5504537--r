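#' Generate the geography dimension
#'
#' Builds a synthetic world geography as a strict hierarchy
#' region -> subregion -> country, with one continental region per ethnic
#' group (Europe/EUR, Americas/AMR, Asia/EAS, Africa/AFR). Country
#' populations are drawn from a heavy-tailed log-normal law so that
#' population-weighted country assignment is nontrivial.
#'
#' @param n_countries Number of countries (>= 4, so every ethnic group is
#'   covered by at least one country).
#' @param seed Integer seed; the table is bit-reproducible under it.
#' @return A data.frame with columns `geo_id`, `country`, `subregion`,
#'   `region`, `population`, `ethnic_group`.
#' @export
generate_geography <- function(n_countries, seed) {
  stopifnot_scalar_number(n_countries, "n_countries", min = 1)
  if (n_countries < 4) stop("n_countries must be >= 4 to cover the four ethnic groups")
  n_countries <- as.integer(n_countries)
  groups <- ethnic_groups()
  regions <- region_of_group()
  withr::with_seed(as.integer(seed), {
    # round-robin region assignment guarantees >= 1 country per region
    grp <- groups[((seq_len(n_countries) - 1L) %% 4L) + 1L]
    region <- unname(regions[grp])
    # a handful of subregions per region
    sub_idx <- integer(n_countries)
    for (r in unique(region)) {
      in_r <- which(region == r)
      n_sub <- max(1L, ceiling(length(in_r) / 8))
      sub_idx[in_r] <- sample.int(n_sub, length(in_r), replace = TRUE)
    }
    population <- as.integer(pmin(
      round(stats::rlnorm(n_countries, meanlog = log(8e6), sdlog = 1.6)) + 1e5,
      1.4e9
    ))
    data.frame(
      geo_id = seq_len(n_countries),
      country = sprintf("country_%03d", seq_len(n_countries)),
      subregion = sprintf("%s_sub%02d", region, sub_idx),
      region = region,
      population = population,
      ethnic_group = grp,
      stringsAsFactors = FALSE
    )
  })
}

# latent gene layout shared by both annotation sources: loci + union exons
latent_gene_layout <- function(n_genes, exons_per_gene_mean, seed) {
  lens <- chrom_lengths_mb()
  withr::with_seed(as.integer(seed), {
    chrom <- sample(names(lens), n_genes, replace = TRUE, prob = lens)
    k <- 1L + stats::rpois(n_genes, max(exons_per_gene_mean - 1, 0))
    genes <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      exon_len <- pmax(50L, as.integer(round(stats::rlnorm(k[g], log(160), 0.4))))
      gap <- if (k[g] > 1L) 200L + as.integer(round(stats::rexp(k[g] - 1L, 1 / 2000))) else integer(0)
      start_rel <- cumsum(c(0L, exon_len[-k[g]] + gap))
      genes[[g]] <- list(chrom = chrom[g], start_rel = start_rel,
                         end_rel = start_rel + exon_len - 1L)
    }
    # lay genes on each chromosome sequentially, no overlap, random spacing
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      offset <- 10000L
      spacing <- 1000L + as.integer(round(stats::rexp(length(idx), 1 / 10000)))
      for (j in seq_along(idx)) {
        g <- idx[j]
        genes[[g]]$start <- genes[[g]]$start_rel + offset
        genes[[g]]$end <- genes[[g]]$end_rel + offset
        offset <- genes[[g]]$end[length(genes[[g]]$end)] + spacing[j]
      }
      if (offset > lens[[ch]] * 1e6) {
        stop("requested genes exceed available coordinate space on chromosome ", ch)
      }
    }
    lapply(seq_len(n_genes), function(g) {
      list(gene_symbol = sprintf("GENE%04d", g), chrom = genes[[g]]$chrom,
           exon_start = genes[[g]]$start, exon_end = genes[[g]]$end)
    })
  })
}

#' Generate an exon-level gene-model dimension
#'
#' Produces one row per (transcript, exon) for a synthetic annotation source.
#' Each gene carries one canonical transcript, possibly an alternative
#' transcript using a subset of the gene's exons, and exactly one merged
#' transcript whose exons cover the union of the gene's exons. The two
#' sources (`ensembl`, `refseq`) realize transcript structure independently
#' over a shared latent exon layout (derived from `seed` alone), with the
#' refseq source padding exon bounds by a small flank, so that any position
#' inside a merged exon of one source also falls inside a merged exon of the
#' other.
#'
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene_mean Mean exon count per gene.
#' @param seed Integer seed.
#' @param source `"ensembl"` or `"refseq"`.
#' @return A data.frame with columns `region_id`, `source`, `gene_symbol`,
#'   `transcript_id`, `exon_number`, `chrom`, `start`, `end`,
#'   `is_canonical`, `is_merged`.
#' @export
generate_gene_model <- function(n_genes, exons_per_gene_mean = 8, seed,
                                source = c("ensembl", "refseq")) {
  source <- match.arg(source)
  stopifnot_scalar_number(n_genes, "n_genes", min = 1)
  n_genes <- as.integer(n_genes)
  latent <- latent_gene_layout(n_genes, exons_per_gene_mean, seed)
  flank <- if (source == "refseq") 10L else 0L
  prefix <- if (source == "refseq") "RST" else "ENT"
  src_seed <- as.integer(seed) + if (source == "refseq") 2L else 1L
  withr::with_seed(src_seed, {
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gene <- latent[[g]]
      k <- length(gene$exon_start)
      s <- pmax(1L, gene$exon_start - flank)
      e <- gene$exon_end + flank
      tx <- list()
      # canonical transcript spans all exons of the gene
      tx[[1]] <- list(id = sprintf("%s%04d.1", prefix, g), exons = seq_len(k),
                      canonical = TRUE, merged = FALSE)
      if (k > 1L && stats::runif(1) < 0.6) {
        keep <- which(stats::runif(k) < 0.75)
        if (length(keep) == 0L) keep <- sample.int(k, 1L)
        tx[[2]] <- list(id = sprintf("%s%04d.2", prefix, g), exons = sort(keep),
                        canonical = FALSE, merged = FALSE)
      }
      tx[[length(tx) + 1L]] <- list(id = sprintf("%s%04d.M", prefix, g),
                                    exons = seq_len(k), canonical = FALSE,
                                    merged = TRUE)
      rows[[g]] <- do.call(rbind, lapply(tx, function(t) {
        data.frame(
          source = source, gene_symbol = gene$gene_symbol,
          transcript_id = t$id,
          exon_number = seq_along(t$exons),
          chrom = gene$chrom,
          start = s[t$exons], end = e[t$exons],
          is_canonical = t$canonical, is_merged = t$merged,
          stringsAsFactors = FALSE
        )
      }))
    }
    out <- do.call(rbind, rows)
    out <- cbind(region_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Hyperparameters of the allele-frequency model
#'
#' The per-variant base allele frequency is drawn from a right-skewed Beta
#' law (most variants rare), and per-ethnic-group frequencies are obtained by
#' jittering the base on the logit scale, giving positive cross-group
#' correlation. Setting `fixed` short-circuits both draws (useful for
#' degenerate fixtures).
#'
#' @param base_shape1,base_shape2 Beta shape parameters of the base AF
#'   (default mean ~0.048).
#' @param group_logit_sd Standard deviation of the per-group logit jitter.
#' @param fixed If non-NULL, every group's AF is exactly this value.
#' @return A list of class `af_hyperparams`.
#' @export
af_hyperparams <- function(base_shape1 = 0.3, base_shape2 = 6,
                           group_logit_sd = 0.5, fixed = NULL) {
  structure(list(base_shape1 = base_shape1, base_shape2 = base_shape2,
                 group_logit_sd = group_logit_sd, fixed = fixed),
            class = "af_hyperparams")
}

#' Generate the variant catalog and predictor dimension
#'
#' Places `n_variants` unique SNVs inside merged-transcript exons of the
#' supplied gene model (exons sampled proportionally to length, positions
#' uniformly within the exon), draws per-ethnic-group allele frequencies
#' under the `af_hyperparams` model, flags approximately `damaging_fraction`
#' of variants as damaging, and draws a positive per-site mean depth of
#' coverage from a Gamma law.
#'
#' @param gene_model A gene-model data.frame from [generate_gene_model()]
#'   (its merged-transcript exons define the admissible positions).
#' @param n_variants Number of variants (>= 0; 0 yields an empty catalog).
#' @param af Hyperparameters from [af_hyperparams()].
#' @param damaging_fraction Probability a variant is flagged damaging.
#' @param seed Integer seed.
#' @param depth_mean,depth_shape Gamma parameters of the per-site mean depth
#'   (mean `depth_mean`, shape `depth_shape`).
#' @return A list with `catalog` (columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `af_EUR`, `af_AMR`, `af_EAS`, `af_AFR`,
#'   `fathmm_damaging`, `mean_dp`, `prediction_fk`) and `predictions`
#'   (the one-row-per-variant predictor dimension).
#' @export
generate_catalog <- function(gene_model, n_variants, af = af_hyperparams(),
                             damaging_fraction = 0.1, seed,
                             depth_mean = 60, depth_shape = 8) {
  if (is.null(gene_model) || nrow(gene_model) == 0L) {
    stop("gene_model is empty; generate it first")
  }
  stopifnot_scalar_number(n_variants, "n_variants", min = 0)
  n_variants <- as.integer(n_variants)
  groups <- ethnic_groups()
  af_cols <- paste0("af_", groups)
  empty <- data.frame(
    variant_id = integer(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0),
    af_EUR = numeric(0), af_AMR = numeric(0), af_EAS = numeric(0),
    af_AFR = numeric(0), fathmm_damaging = logical(0), mean_dp = numeric(0),
    prediction_fk = integer(0), stringsAsFactors = FALSE
  )
  if (n_variants == 0L) {
    return(list(catalog = empty,
                predictions = data.frame(prediction_fk = integer(0),
                                         fathmm_damaging = logical(0),
                                         fathmm_score = numeric(0),
                                         sift_score = numeric(0),
                                         polyphen_score = numeric(0))))
  }
  exons <- gene_model[gene_model$is_merged, , drop = FALSE]
  exon_len <- exons$end - exons$start + 1L
  if (n_variants > sum(exon_len)) {
    stop("n_variants exceeds the available exonic coordinate space")
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(nrow(exons), n_variants, replace = TRUE, prob = exon_len)
    pos <- exons$start[idx] + as.integer(floor(stats::runif(n_variants) * exon_len[idx]))
    chrom <- exons$chrom[idx]
    # resample duplicate (chrom, pos) sites until all unique
    for (iter in 1:1000) {
      dup <- duplicated(paste(chrom, pos))
      if (!any(dup)) break
      j <- which(dup)
      r <- sample.int(nrow(exons), length(j), replace = TRUE, prob = exon_len)
      pos[j] <- exons$start[r] + as.integer(floor(stats::runif(length(j)) * exon_len[r]))
      chrom[j] <- exons$chrom[r]
    }
    if (anyDuplicated(paste(chrom, pos))) {
      stop("could not place ", n_variants, " unique variants; reduce n_variants")
    }
    ref <- sample(bases, n_variants, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
    if (!is.null(af$fixed)) {
      afm <- matrix(af$fixed, n_variants, 4)
    } else {
      base <- stats::rbeta(n_variants, af$base_shape1, af$base_shape2)
      base <- pmin(pmax(base, 1e-4), 1 - 1e-4)
      afm <- vapply(seq_len(4), function(j) {
        stats::plogis(stats::qlogis(base) + stats::rnorm(n_variants, 0, af$group_logit_sd))
      }, numeric(n_variants))
      afm <- matrix(afm, n_variants, 4)
    }
    damaging <- stats::runif(n_variants) < damaging_fraction
    mean_dp <- stats::rgamma(n_variants, shape = depth_shape,
                             rate = depth_shape / depth_mean)
    mean_dp <- pmax(mean_dp, 1)
    ord <- order(chrom_rank(chrom), pos)
    catalog <- data.frame(
      variant_id = seq_len(n_variants), chrom = chrom[ord], pos = pos[ord],
      ref = ref[ord], alt = alt[ord], stringsAsFactors = FALSE
    )
    afm <- afm[ord, , drop = FALSE]
    for (j in seq_along(groups)) catalog[[af_cols[j]]] <- afm[, j]
    catalog$fathmm_damaging <- damaging[ord]
    catalog$mean_dp <- mean_dp[ord]
    catalog$prediction_fk <- catalog$variant_id
    predictions <- data.frame(
      prediction_fk = catalog$variant_id,
      fathmm_damaging = catalog$fathmm_damaging,
      fathmm_score = stats::runif(n_variants),
      sift_score = stats::runif(n_variants),
      polyphen_score = stats::runif(n_variants)
    )
    list(catalog = catalog, predictions = predictions)
  })
}

#' Generate the disease dimension
#'
#' Synthetic Mendelian-disease catalog with unique 6-digit OMIM-like ids.
#'
#' @param n_diseases Number of diseases (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `disease_id`, `omim_id`, `name`.
#' @export
generate_diseases <- function(n_diseases, seed) {
  stopifnot_scalar_number(n_diseases, "n_diseases", min = 0)
  n_diseases <- as.integer(n_diseases)
  if (n_diseases == 0L) {
    return(data.frame(disease_id = integer(0), omim_id = character(0),
                      name = character(0), stringsAsFactors = FALSE))
  }
  withr::with_seed(as.integer(seed), {
    omim <- sample(100000:999999, n_diseases)
    data.frame(
      disease_id = seq_len(n_diseases),
      omim_id = sprintf("%06d", omim),
      name = sprintf("disease_%05d", seq_len(n_diseases)),
      stringsAsFactors = FALSE
    )
  })
}
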
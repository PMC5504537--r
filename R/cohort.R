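#' Hardy-Weinberg genotype probabilities
#'
#' For an allele frequency `af`, the probability of genotypes 0/0, 0/1 and
#' 1/1 under Hardy-Weinberg equilibrium:
#' \deqn{p(0/0) = 1 - 2 af + af^2, \quad p(0/1) = 2 af (1 - af), \quad
#'   p(1/1) = af^2.}
#'
#' @param af Numeric vector of allele frequencies in \[0, 1\].
#' @return A matrix with one row per element of `af` and columns
#'   `p_homref`, `p_het`, `p_homalt` (each row sums to 1).
#' @export
genotype_probabilities <- function(af) {
  if (!is.numeric(af) || length(af) == 0L || anyNA(af) || any(af < 0 | af > 1)) {
    stop("`af` must be numeric in [0, 1]")
  }
  cbind(p_homref = 1 - 2 * af + af^2,
        p_het = 2 * af * (1 - af),
        p_homalt = af^2)
}

#' Draw genotypes from allele frequencies
#'
#' Samples one genotype per element of `af` with the Hardy-Weinberg
#' probabilities of [genotype_probabilities()], using the current RNG state.
#'
#' @param af Numeric vector of allele frequencies in \[0, 1\].
#' @return Character vector over `{"HOM_REF", "HET", "HOM_ALT"}`.
#' @export
simulate_genotype <- function(af) {
  p <- genotype_probabilities(af)
  u <- stats::runif(length(af))
  out <- rep("HOM_REF", length(af))
  out[u >= p[, "p_homref"]] <- "HET"
  out[u >= p[, "p_homref"] + p[, "p_het"]] <- "HOM_ALT"
  out
}

#' Simulate total and allelic depth of coverage
#'
#' Total depth is Poisson with the site mean; alt-supporting reads are
#' Binomial(dp, 1/2) for heterozygotes and dp minus a Binomial(dp, eps)
#' error count for alt homozygotes. Always 0 <= ad_alt <= dp.
#'
#' @param mean_dp Positive per-site mean depth (vector, recycled against
#'   `genotype`).
#' @param genotype Character vector over `{"HET", "HOM_ALT"}`.
#' @param eps Read error rate for HOM_ALT sites.
#' @return A data.frame with columns `dp` and `ad_alt`.
#' @export
simulate_depth <- function(mean_dp, genotype, eps = 0.01) {
  if (any(mean_dp <= 0)) stop("`mean_dp` must be > 0")
  if (any(!genotype %in% c("HET", "HOM_ALT"))) {
    stop("depth is simulated only for non-reference genotypes")
  }
  n <- max(length(mean_dp), length(genotype))
  mean_dp <- rep_len(mean_dp, n)
  genotype <- rep_len(genotype, n)
  dp <- stats::rpois(n, mean_dp)
  ad <- integer(n)
  het <- genotype == "HET"
  if (any(het)) ad[het] <- stats::rbinom(sum(het), dp[het], 0.5)
  if (any(!het)) ad[!het] <- dp[!het] - stats::rbinom(sum(!het), dp[!het], eps)
  data.frame(dp = dp, ad_alt = ad)
}

#' Assign samples to populations, countries and diseases
#'
#' Each sample is assigned an ethnic group according to `ethnic_proportions`,
#' then a country within that group's region, drawn multinomially with
#' weights proportional to country population sizes. A disease is attached
#' with probability `disease_prevalence`, uniformly over the disease
#' dimension.
#'
#' @param n_samples Number of samples.
#' @param ethnic_proportions Named numeric vector over [ethnic_groups()]
#'   summing to 1 (default uniform).
#' @param geography Geography dimension from [generate_geography()].
#' @param diseases Disease dimension from [generate_diseases()].
#' @param disease_prevalence Probability a sample carries a disease label.
#' @param seed Integer seed.
#' @return A data.frame with columns `sample_id`, `ethnic_group`, `geo_fk`,
#'   `disease_fk` (NA when the sample carries no disease label).
#' @export
assign_samples <- function(n_samples,
                           ethnic_proportions = stats::setNames(rep(0.25, 4), ethnic_groups()),
                           geography, diseases = NULL,
                           disease_prevalence = 0, seed) {
  stopifnot_scalar_number(n_samples, "n_samples", min = 1)
  groups <- ethnic_groups()
  props <- ethnic_proportions[groups]
  if (anyNA(props) || abs(sum(props) - 1) > 1e-8) {
    stop("`ethnic_proportions` must be named over the four ethnic groups and sum to 1")
  }
  for (g in groups) {
    if (props[[g]] > 0 && !any(geography$ethnic_group == g)) {
      stop("ethnic group ", g, " has positive proportion but no countries")
    }
  }
  n_samples <- as.integer(n_samples)
  n_dis <- if (is.null(diseases)) 0L else nrow(diseases)
  withr::with_seed(as.integer(seed), {
    grp <- sample(groups, n_samples, replace = TRUE, prob = props)
    geo_fk <- integer(n_samples)
    for (g in unique(grp)) {
      rows <- which(geography$ethnic_group == g)
      i <- which(grp == g)
      geo_fk[i] <- geography$geo_id[
        if (length(rows) == 1L) rep(rows, length(i))
        else rows[sample.int(length(rows), length(i), replace = TRUE,
                             prob = geography$population[rows])]
      ]
    }
    disease_fk <- rep(NA_integer_, n_samples)
    if (disease_prevalence > 0 && n_dis > 0L) {
      has <- stats::runif(n_samples) < disease_prevalence
      disease_fk[has] <- diseases$disease_id[
        sample.int(n_dis, sum(has), replace = TRUE)]
    }
    data.frame(sample_id = seq_len(n_samples), ethnic_group = grp,
               geo_fk = geo_fk, disease_fk = disease_fk,
               stringsAsFactors = FALSE)
  })
}

# resolve each catalog variant to the containing exon of the merged
# transcript of its gene, for one annotation source; errors if any variant
# is not contained (violation of the generator contract)
resolve_region_fks <- function(catalog, gene_model) {
  exons <- gene_model[gene_model$is_merged, , drop = FALSE]
  fk <- rep(NA_integer_, nrow(catalog))
  for (ch in unique(catalog$chrom)) {
    vi <- which(catalog$chrom == ch)
    ei <- which(exons$chrom == ch)
    if (length(ei) == 0L) next
    # merged exons within a source are disjoint: findInterval on sorted starts
    o <- ei[order(exons$start[ei])]
    j <- findInterval(catalog$pos[vi], exons$start[o])
    ok <- j >= 1L & catalog$pos[vi] <= ifelse(j >= 1L, exons$end[o][pmax(j, 1L)], -1L)
    fk[vi[ok]] <- exons$region_id[o][j[ok]]
  }
  if (anyNA(fk)) {
    stop(sum(is.na(fk)), " catalog variant(s) not contained in any merged exon of source ",
         gene_model$source[1])
  }
  fk
}

#' Simulate the genotype-call fact stream for a cohort
#'
#' For every (sample, catalog variant) pair an independent genotype is drawn
#' under Hardy-Weinberg with the allele frequency of the sample's ethnic
#' group; only non-reference calls (HET, HOM_ALT) are emitted, each with
#' simulated total and allelic depth. Gene-model foreign keys point at the
#' containing exon of the merged transcript of the variant's gene, for both
#' annotation sources. Output is ordered by (sample_id, chrom, pos) and is
#' bit-reproducible under `seed`.
#'
#' @param catalog Variant catalog from [generate_catalog()].
#' @param samples Sample registry from [assign_samples()].
#' @param gene_models Named list with elements `ensembl` and `refseq`, each
#'   from [generate_gene_model()].
#' @param seed Integer seed.
#' @param eps Read error rate for HOM_ALT allelic depth.
#' @return A data.frame of fact records: `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `genotype`, `dp`, `ad_alt`, `gl` (placeholder, NA), `geo_fk`,
#'   `region_fk_ens`, `region_fk_rs`, `disease_fk`, `prediction_fk`.
#' @export
simulate_cohort <- function(catalog, samples, gene_models, seed, eps = 0.01) {
  n_v <- nrow(catalog)
  empty <- data.frame(
    sample_id = integer(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), genotype = character(0),
    dp = integer(0), ad_alt = integer(0), gl = numeric(0),
    geo_fk = integer(0), region_fk_ens = integer(0), region_fk_rs = integer(0),
    disease_fk = integer(0), prediction_fk = integer(0),
    stringsAsFactors = FALSE
  )
  if (n_v == 0L || nrow(samples) == 0L) return(empty)
  fk_ens <- resolve_region_fks(catalog, gene_models$ensembl)
  fk_rs <- resolve_region_fks(catalog, gene_models$refseq)
  afm <- as.matrix(catalog[paste0("af_", ethnic_groups())])
  colnames(afm) <- ethnic_groups()
  withr::with_seed(as.integer(seed), {
    per_sample <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      af <- afm[, samples$ethnic_group[s]]
      gt <- simulate_genotype(af)
      nz <- which(gt != "HOM_REF")
      if (length(nz) == 0L) next
      depth <- simulate_depth(catalog$mean_dp[nz], gt[nz], eps = eps)
      per_sample[[s]] <- data.frame(
        sample_id = samples$sample_id[s],
        chrom = catalog$chrom[nz], pos = catalog$pos[nz],
        ref = catalog$ref[nz], alt = catalog$alt[nz],
        genotype = gt[nz], dp = depth$dp, ad_alt = depth$ad_alt,
        gl = NA_real_,
        geo_fk = samples$geo_fk[s],
        region_fk_ens = fk_ens[nz], region_fk_rs = fk_rs[nz],
        disease_fk = samples$disease_fk[s],
        prediction_fk = catalog$prediction_fk[nz],
        stringsAsFactors = FALSE
      )
    }
    per_sample <- per_sample[!vapply(per_sample, is.null, logical(1))]
    if (length(per_sample) == 0L) {
      empty
    } else {
      fact <- do.call(rbind, per_sample)
      fact <- fact[order(fact$sample_id, chrom_rank(fact$chrom), fact$pos), ]
      rownames(fact) <- NULL
      fact
    }
  })
}
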
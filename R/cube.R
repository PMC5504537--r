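cube_key <- function(by) if (length(by) == 0L) "<apex>" else paste(by, collapse = "|")

cube_measures_all <- function() {
  c("n_het", "n_homalt", "n_records", "allele_count", "n_variants")
}

cube_groupby <- function(level3, by, measures) {
  vkey <- paste(level3$chrom, level3$pos, level3$ref, level3$alt, sep = ":")
  d <- level3
  d$..vkey <- vkey
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_het = sum(n_het), n_homalt = sum(n_homalt),
      n_records = sum(n_het + n_homalt),
      allele_count = sum(n_het + 2 * n_homalt),
      n_variants = dplyr::n_distinct(..vkey),
      .groups = "drop"
    ) |>
    as.data.frame()
  out[c(by, measures)]
}

#' Materialize an aggregate cube over declared hierarchies (storage level 4)
#'
#' Precomputes group-by results of the denormalized level-3 counts table for
#' every prefix of every declared dimension hierarchy (plus the apex, the
#' grand total), keyed for direct lookup. This is an embedded key-value
#' materialization standing in for a distributed OLAP cube: any query whose
#' grouping set is a declared prefix is answered without touching the
#' underlying tables; anything else yields an explicit reroute signal.
#'
#' @param level3 Denormalized counts table from [build_agg_denorm()].
#' @param hierarchies Named list of character vectors, each an ordered
#'   hierarchy of level-3 columns (default: geography
#'   region > subregion > country and the ensembl gene > transcript > exon).
#' @param measures Character vector of measures to precompute, a subset of
#'   `n_het`, `n_homalt`, `n_records`, `allele_count`, `n_variants`.
#' @return An object of class `variant_cube`.
#' @export
build_cube <- function(level3,
                       hierarchies = list(
                         geography = c("region", "subregion", "country"),
                         gene_ens = c("gene_symbol_ens", "transcript_id_ens",
                                      "exon_number_ens")),
                       measures = cube_measures_all()) {
  measures <- match.arg(measures, cube_measures_all(), several.ok = TRUE)
  patterns <- list(character(0))
  for (h in hierarchies) {
    for (i in seq_along(h)) patterns[[length(patterns) + 1L]] <- h[seq_len(i)]
  }
  patterns <- unique(patterns)
  cuboids <- stats::setNames(
    lapply(patterns, function(by) cube_groupby(level3, by, measures)),
    vapply(patterns, cube_key, character(1))
  )
  structure(list(cuboids = cuboids, hierarchies = hierarchies,
                 measures = measures),
            class = "variant_cube")
}

#' Look up a precomputed cuboid
#'
#' @param cube A `variant_cube` from [build_cube()].
#' @param by Character vector of grouping columns (empty for the grand
#'   total). Must be a declared hierarchy prefix.
#' @param where Optional named list of equality filters on the grouping
#'   columns.
#' @return The precomputed group-by data.frame, or a `cube_reroute` object
#'   when the pattern is not declared (caller should fall back to level 3).
#' @export
cube_lookup <- function(cube, by = character(0), where = NULL) {
  stopifnot(inherits(cube, "variant_cube"))
  key <- cube_key(by)
  if (!key %in% names(cube$cuboids)) {
    return(structure(list(by = by), class = "cube_reroute"))
  }
  out <- cube$cuboids[[key]]
  if (!is.null(where)) {
    bad <- setdiff(names(where), by)
    if (length(bad)) {
      return(structure(list(by = by, where = names(where)), class = "cube_reroute"))
    }
    for (nm in names(where)) out <- out[out[[nm]] == where[[nm]], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Test for a cube reroute signal
#'
#' @param x Any object.
#' @return TRUE if `x` signals that the requested pattern is not answerable
#'   from the cube.
#' @export
is_cube_reroute <- function(x) inherits(x, "cube_reroute")

#' @export
print.variant_cube <- function(x, ...) {
  cat("<variant_cube>", length(x$cuboids), "cuboids over",
      length(x$hierarchies), "hierarchies; measures:",
      paste(x$measures, collapse = ", "), "\n")
  invisible(x)
}
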
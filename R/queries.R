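#' Load the query suite descriptors
#'
#' Reads the per-query YAML descriptors shipped under `inst/queries/` (id,
#' applicable storage levels, parameters with defaults, template paths,
#' post-processing step).
#'
#' @return A named list of query descriptors, keyed by query id.
#' @export
query_specs <- function() {
  dir <- system.file("queries", package = "varwarehouse")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  specs <- lapply(files, yaml::read_yaml)
  specs <- stats::setNames(specs, vapply(specs, `[[`, character(1), "id"))
  ids <- c("Q1A", "Q1B", "Q2A", "Q2B", "Q3A", "Q3B", "Q4A", "Q4B",
           paste0("Q", 5:12))
  specs[ids]
}

#' Query ids of the benchmark suite
#'
#' @return Character vector of the 16 query ids (12 query types; the four
#'   complex families each have A/B subqueries).
#' @export
query_ids <- function() names(query_specs())

query_spec <- function(query_id) {
  specs <- query_specs()
  if (!query_id %in% names(specs)) stop("unknown query id: ", query_id)
  specs[[query_id]]
}

# merge user params over YAML defaults; NULL-default params are required
merge_params <- function(spec, params) {
  defaults <- spec$params
  if (length(defaults) == 0L) defaults <- list()
  out <- utils::modifyList(defaults, params[names(params) %in% names(defaults)])
  extra <- setdiff(names(params), names(defaults))
  if (length(extra)) stop("unknown parameter(s) for ", spec$id, ": ", toString(extra))
  missing <- names(out)[vapply(out, is.null, logical(1))]
  if (length(missing)) {
    stop("missing required parameter(s) for ", spec$id, ": ", toString(missing))
  }
  out
}

dim_gp_table <- function(source) {
  switch(source,
         ensembl = "dim_genomic_position_ensembl",
         refseq = "dim_genomic_position_refseq",
         stop("`source` must be 'ensembl' or 'refseq'"))
}

#' Render a query template to executable SQL
#'
#' Substitutes structural tokens (the gene-model source table) from a
#' whitelist, then binds value parameters injection-safely with
#' [DBI::sqlInterpolate()].
#'
#' @param query_id Query id (see [query_ids()]).
#' @param level Storage level: `"raw"`, `"aggr"` or `"aggr_denorm"`.
#' @param dialect SQL dialect (only `"sqlite"` ships; templates are ANSI-ish).
#' @param params Named list of parameter values; defaults come from the
#'   query's YAML descriptor.
#' @return A length-1 character string of SQL.
#' @export
render_query <- function(query_id, level = "raw", dialect = "sqlite",
                         params = list()) {
  spec <- query_spec(query_id)
  if (!level %in% unlist(spec$levels)) {
    stop("query ", query_id, " is not supported on storage level '", level, "'")
  }
  if (!identical(dialect, "sqlite")) stop("unknown dialect: ", dialect)
  params <- merge_params(spec, params)
  tpl_path <- system.file(spec$templates[[level]], package = "varwarehouse")
  if (!nzchar(tpl_path)) stop("missing template for ", query_id, "/", level)
  sql <- paste(readLines(tpl_path), collapse = "\n")
  if (grepl("{{dim_gp}}", sql, fixed = TRUE)) {
    sql <- gsub("{{dim_gp}}", dim_gp_table(params$source), sql, fixed = TRUE)
  }
  params$source <- NULL
  used <- unique(regmatches(sql, gregexpr("\\?[a-zA-Z_]+", sql))[[1]])
  used <- sub("^\\?", "", used)
  absent <- setdiff(used, names(params))
  if (length(absent)) stop("missing required parameter(s): ", toString(absent))
  if (length(used)) {
    sql <- DBI::sqlInterpolate(DBI::ANSI(), sql, .dots = params[used])
  }
  as.character(sql)
}

# weighted type-7 quantiles from a (group cols..., dp, n) histogram; the
# convention (linear interpolation between closest ranks) matches
# stats::quantile(type = 7)
dp_quantiles_postprocess <- function(df) {
  group_cols <- setdiff(names(df), c("dp", "n"))
  split_idx <- if (length(group_cols)) {
    split(seq_len(nrow(df)), df[group_cols], drop = TRUE)
  } else list(seq_len(nrow(df)))
  rows <- lapply(split_idx, function(i) {
    x <- rep(df$dp[i], df$n[i])
    q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    cbind(df[i[1], group_cols, drop = FALSE],
          data.frame(min_dp = q[1], q25_dp = q[2], median_dp = q[3],
                     q75_dp = q[4], max_dp = q[5]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

apply_postprocess <- function(spec, df) {
  pp <- spec$postprocess
  if (is.null(pp)) return(df)
  switch(pp,
         dp_quantiles = dp_quantiles_postprocess(df),
         stop("unknown postprocess step: ", pp))
}
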
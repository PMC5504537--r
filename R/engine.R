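#' The embedded SQL engine adapter
#'
#' Engine adapters satisfy a minimal contract: open a session over a
#' warehouse (registering the tables a storage level needs), submit SQL
#' text, fetch typed rows, close. The default adapter is the embedded
#' SQLite engine over the warehouse's columnar files; further adapters
#' (e.g. remote JDBC-style endpoints) can be plugged in by implementing the
#' same generics.
#'
#' @return An engine adapter object with label `"sqlite"`.
#' @export
sqlite_engine <- function() {
  structure(list(label = "sqlite"), class = c("sqlite_engine", "engine_adapter"))
}

level_tables <- function(level) {
  base <- c("dim_geography", "dim_genomic_position_ensembl",
            "dim_genomic_position_refseq", "dim_disease",
            "dim_variant_predictions", "samples")
  switch(level,
         raw = c(base, "fact"),
         aggr = c(base, "fact_agg_counts", "fact_agg_depth"),
         aggr_denorm = c(base, "fact_agg_counts_dims", "fact_agg_depth_dims"),
         stop("unknown storage level: ", level))
}

#' Open an engine session over a warehouse storage level
#'
#' @param engine Engine adapter (see [sqlite_engine()]).
#' @param dir Warehouse directory.
#' @param level Storage level to register tables for.
#' @param format,codec Physical table variant to load.
#' @return An `engine_session` object.
#' @export
engine_open <- function(engine, dir, level = "raw", format = "parquet",
                        codec = NULL) {
  UseMethod("engine_open")
}

#' @export
engine_open.sqlite_engine <- function(engine, dir, level = "raw",
                                      format = "parquet", codec = NULL) {
  conn <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  for (tbl in level_tables(level)) {
    df <- wh_read(dir, tbl, format = format, codec = codec)
    DBI::dbWriteTable(conn, tbl, df)
  }
  for (idx in c("fact", "fact_agg_counts", "fact_agg_depth",
                "fact_agg_counts_dims", "fact_agg_depth_dims")) {
    if (DBI::dbExistsTable(conn, idx)) {
      DBI::dbExecute(conn, sprintf(
        "CREATE INDEX idx_%s_pos ON %s (chrom, pos)", idx, idx))
    }
  }
  if (DBI::dbExistsTable(conn, "fact")) {
    DBI::dbExecute(conn, "CREATE INDEX idx_fact_sample ON fact (sample_id)")
  }
  for (gp in c("dim_genomic_position_ensembl", "dim_genomic_position_refseq")) {
    DBI::dbExecute(conn, sprintf(
      'CREATE INDEX idx_%s ON %s (chrom, "start", "end")', gp, gp))
  }
  structure(list(engine = engine$label, conn = conn, level = level,
                 format = format, codec = codec),
            class = "engine_session")
}

#' Submit SQL text to an open engine session
#'
#' @param session An `engine_session`.
#' @param sql SQL text.
#' @return A data.frame of typed rows.
#' @export
engine_submit <- function(session, sql) {
  stopifnot(inherits(session, "engine_session"))
  DBI::dbGetQuery(session$conn, sql)
}

#' Close an engine session
#'
#' @param session An `engine_session`.
#' @return NULL, invisibly.
#' @export
engine_close <- function(session) {
  if (inherits(session, "engine_session")) DBI::dbDisconnect(session$conn)
  invisible(NULL)
}

#' Execute a benchmark query through an engine session
#'
#' Renders the query for the session's storage level, submits it, applies
#' the query's dialect post-processing step (if any) and canonicalizes the
#' result so it is directly comparable with [oracle_query()] output. Engine
#' errors are re-signalled with the rendered SQL attached.
#'
#' @param session An open `engine_session` (see [engine_open()]).
#' @param query_id Query id.
#' @param params Named list of query parameters.
#' @return A canonically ordered data.frame.
#' @export
execute_query <- function(session, query_id, params = list()) {
  spec <- query_spec(query_id)
  sql <- render_query(query_id, level = session$level, params = params)
  df <- tryCatch(engine_submit(session, sql), error = function(e) {
    stop("engine error for ", query_id, " [", session$level, "]: ",
         conditionMessage(e), "\n--- rendered SQL ---\n", sql, call. = FALSE)
  })
  df <- apply_postprocess(spec, df)
  canonicalize_result(df)
}
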
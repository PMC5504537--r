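#' Read a benchmark configuration file
#'
#' The YAML schema (see README) lists the queries (id, optional levels,
#' params), engine labels, physical formats (format + codec), storage
#' levels, repetition count and verification switch.
#'
#' @param path Path to a YAML file.
#' @return A validated config list.
#' @export
read_bench_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_bench_config(cfg)
}

validate_bench_config <- function(cfg) {
  cfg$repetitions <- cfg$repetitions %||% 5L
  if (!is.numeric(cfg$repetitions) || cfg$repetitions < 1) {
    stop("`repetitions` must be >= 1")
  }
  cfg$repetitions <- as.integer(cfg$repetitions)
  cfg$engines <- cfg$engines %||% list("sqlite")
  cfg$formats <- cfg$formats %||% list(list(format = "parquet", codec = "snappy"))
  cfg$levels <- cfg$levels %||% list("raw")
  cfg$verify <- isTRUE(cfg$verify)
  if (is.null(cfg$queries) || length(cfg$queries) == 0L) {
    stop("config lists no queries")
  }
  cfg
}

make_engine <- function(label) {
  switch(label, sqlite = sqlite_engine(),
         stop("unknown engine adapter: ", label))
}

timing_record <- function(query_id, engine, format, codec, level, rep,
                          wall_seconds = NA_real_, row_count = NA_integer_,
                          status = "ok") {
  data.frame(query_id = query_id, engine = engine, format = format,
             codec = codec, level = level, rep = rep,
             wall_seconds = wall_seconds, row_count = row_count,
             status = status, stringsAsFactors = FALSE)
}

#' Run a benchmark configuration over a warehouse
#'
#' Executes every (query, engine, format, codec, level) combination
#' `repetitions` times over the read-only warehouse, recording wall time and
#' result cardinality. A failing combination is recorded with status
#' `"failed"` (no wall time) and the run continues. With `verify = TRUE` and
#' a `world` supplied, each result's cardinality is checked against the
#' in-memory oracle; a divergence is flagged as status `"mismatch"`.
#'
#' @param dir Warehouse directory.
#' @param config Config list from [read_bench_config()] (or an equivalent
#'   in-memory list).
#' @param world Optional in-memory world for oracle verification.
#' @param out_csv Optional path; when given, one CSV row per timing record
#'   is written there.
#' @return A data.frame of timing records (columns `query_id`, `engine`,
#'   `format`, `codec`, `level`, `rep`, `wall_seconds`, `row_count`,
#'   `status`).
#' @export
run_bench <- function(dir, config, world = NULL, out_csv = NULL) {
  config <- validate_bench_config(config)
  records <- list()
  for (eng_label in unlist(config$engines)) {
    for (fmt in config$formats) {
      format <- fmt$format %||% "parquet"
      codec <- fmt$codec %||% "snappy"
      for (level in unlist(config$levels)) {
        session <- tryCatch(
          engine_open(make_engine(eng_label), dir, level = level,
                      format = format, codec = codec),
          error = function(e) e)
        for (q in config$queries) {
          qid <- q$id
          q_levels <- unlist(q$levels %||% list(level))
          params <- q$params %||% list()
          applicable <- level %in% q_levels
          oracle_n <- NULL
          for (rep in seq_len(config$repetitions)) {
            rec <- if (!applicable) {
              timing_record(qid, eng_label, format, codec, level, rep,
                            status = "skipped")
            } else if (inherits(session, "error")) {
              timing_record(qid, eng_label, format, codec, level, rep,
                            status = "failed")
            } else {
              t0 <- proc.time()[["elapsed"]]
              res <- tryCatch(execute_query(session, qid, params = params),
                              error = function(e) e)
              wall <- proc.time()[["elapsed"]] - t0
              if (inherits(res, "error")) {
                timing_record(qid, eng_label, format, codec, level, rep,
                              status = "failed")
              } else {
                status <- "ok"
                if (config$verify && !is.null(world)) {
                  if (is.null(oracle_n)) {
                    oracle_n <- nrow(oracle_query(qid, params = params,
                                                  world = world))
                  }
                  if (nrow(res) != oracle_n) status <- "mismatch"
                }
                timing_record(qid, eng_label, format, codec, level, rep,
                              wall_seconds = max(wall, .Machine$double.eps),
                              row_count = nrow(res), status = status)
              }
            }
            records[[length(records) + 1L]] <- rec
          }
        }
        if (!inherits(session, "error")) engine_close(session)
      }
    }
  }
  out <- do.call(rbind, records)
  out <- out[out$status != "skipped", , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Summarize timing records per combination
#'
#' @param records Timing records from [run_bench()].
#' @return One row per (query, engine, format, codec, level) with `n_ok`,
#'   mean/min/max wall seconds over successful repetitions, and a `status`
#'   flag (`"ok"` or `"failed"` when no repetition succeeded).
#' @export
summarize_bench <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(data.frame(query_id = character(0), engine = character(0),
                      format = character(0), codec = character(0),
                      level = character(0), n_ok = integer(0),
                      mean_seconds = numeric(0), min_seconds = numeric(0),
                      max_seconds = numeric(0), status = character(0)))
  }
  records |>
    dplyr::group_by(query_id, engine, format, codec, level) |>
    dplyr::summarise(
      n_ok = sum(status == "ok"),
      mean_seconds = if (any(status == "ok")) mean(wall_seconds[status == "ok"]) else NA_real_,
      min_seconds = if (any(status == "ok")) min(wall_seconds[status == "ok"]) else NA_real_,
      max_seconds = if (any(status == "ok")) max(wall_seconds[status == "ok"]) else NA_real_,
      status = if (any(status == "ok")) "ok" else "failed",
      .groups = "drop"
    ) |>
    as.data.frame()
}

query_family <- function(query_id) {
  ifelse(substr(query_id, 1, 2) %in% c("Q1", "Q2", "Q3", "Q4") &
           nchar(query_id) == 3, "Q1-Q4", "Q5-Q12")
}

#' Plot benchmark summaries
#'
#' Grouped bar charts of mean execution time per query, one figure per
#' query family (the complex star queries Q1-Q4 and the fact-only queries
#' Q5-Q12), with error bars spanning the recorded minimum and maximum.
#'
#' @param summary Output of [summarize_bench()].
#' @param out_dir Directory for the figure files (created if needed).
#' @return Invisibly, a named list of ggplot objects (also written as PNG
#'   files into `out_dir`).
#' @export
plot_bench <- function(summary, out_dir) {
  stopifnot(nrow(summary) > 0L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary$family <- query_family(summary$query_id)
  summary$combo <- paste(summary$engine, summary$format, summary$codec,
                         summary$level, sep = "/")
  plots <- list()
  for (fam in unique(summary$family)) {
    d <- summary[summary$family == fam & summary$status == "ok", , drop = FALSE]
    if (nrow(d) == 0L) next
    p <- ggplot2::ggplot(d, ggplot2::aes(x = query_id, y = mean_seconds,
                                         fill = combo)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = min_seconds, ymax = max_seconds),
        position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
      ggplot2::labs(x = "query", y = "execution time [s]",
                    fill = "engine/format/codec/level",
                    title = paste("Benchmark:", fam)) +
      ggplot2::theme_minimal()
    file <- file.path(out_dir, paste0("bench_", gsub("[^A-Za-z0-9]", "_", fam), ".png"))
    ggplot2::ggsave(file, p, width = 9, height = 5, dpi = 120)
    plots[[fam]] <- p
  }
  invisible(plots)
}
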
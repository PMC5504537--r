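#' Chromosome labels in canonical order
#'
#' The 24 human chromosome labels (1-22, X, Y) in their conventional order.
#'
#' @return Character vector of length 24.
#' @export
chromosomes <- function() c(as.character(1:22), "X", "Y")

# approximate chromosome lengths in Mb (GRCh-like proportions); used only to
# weight gene placement and bound coordinate space
chrom_lengths_mb <- function() {
  stats::setNames(
    c(248, 242, 198, 190, 181, 171, 159, 145, 138, 134, 135, 133,
      114, 107, 102, 90, 83, 80, 59, 64, 47, 51, 156, 57),
    chromosomes()
  )
}

chrom_rank <- function(chrom) match(as.character(chrom), chromosomes())

#' Ethnic groups of the simulated population
#'
#' The four ethnic-group labels every sample and allele frequency is keyed on.
#'
#' @return Character vector `c("EUR", "AMR", "EAS", "AFR")`.
#' @export
ethnic_groups <- function() c("EUR", "AMR", "EAS", "AFR")

# 1:1 continental region for each ethnic group
region_of_group <- function() {
  c(EUR = "Europe", AMR = "Americas", EAS = "Asia", AFR = "Africa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a single number >= %s", name, min), call. = FALSE)
  }
}

#' Canonically order a query result
#'
#' Sorts rows by every non-floating-point column (keys are exact; measures are
#' not used for ordering so that tiny numeric differences cannot permute rows)
#' and resets row names. Used before comparing engine output with oracle output.
#'
#' @param df A data.frame.
#' @return The same data.frame, canonically ordered.
#' @export
canonicalize_result <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) <= 1L) {
    rownames(df) <- NULL
    return(df)
  }
  keys <- df[!vapply(df, is.double, logical(1))]
  ord <- if (ncol(keys) > 0L) do.call(order, c(unname(keys), list(method = "radix"))) else seq_len(nrow(df))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Compare two query results up to row order and numeric tolerance
#'
#' @param a,b Data frames with identical column sets.
#' @param tol Relative tolerance for double columns.
#' @return TRUE if equal, otherwise a character description of the first
#'   difference (testthat-friendly).
#' @export
results_equal <- function(a, b, tol = 1e-9) {
  a <- as.data.frame(a)
  b <- as.data.frame(b)
  if (!setequal(names(a), names(b))) {
    return(sprintf("column sets differ: {%s} vs {%s}",
                   toString(names(a)), toString(names(b))))
  }
  b <- b[names(a)]
  if (nrow(a) != nrow(b)) {
    return(sprintf("row counts differ: %d vs %d", nrow(a), nrow(b)))
  }
  if (nrow(a) == 0L) return(TRUE)
  # sort both by the columns that are exact (non-double) in both inputs
  key_cols <- names(a)[!vapply(a, is.double, logical(1)) &
                         !vapply(b, is.double, logical(1))]
  if (length(key_cols) && nrow(a) > 1L) {
    a <- a[do.call(order, c(unname(a[key_cols]), list(method = "radix"))), , drop = FALSE]
    b <- b[do.call(order, c(unname(b[key_cols]), list(method = "radix"))), , drop = FALSE]
  }
  for (nm in names(a)) {
    x <- a[[nm]]; y <- b[[nm]]
    # a SQL NULL with no typed values arrives as logical NA; take the
    # partner column's type
    if (is.logical(x) && all(is.na(x)) && !is.logical(y)) x <- as.vector(x, mode = typeof(y))
    if (is.logical(y) && all(is.na(y)) && !is.logical(x)) y <- as.vector(y, mode = typeof(x))
    if (is.numeric(x) && is.numeric(y)) {
      x <- as.numeric(x); y <- as.numeric(y)
      both_na <- is.na(x) & is.na(y)
      if (any(is.na(x) != is.na(y))) {
        return(sprintf("NA pattern differs in column `%s`", nm))
      }
      xx <- x[!both_na]; yy <- y[!both_na]
      denom <- pmax(abs(xx), abs(yy), 1)
      if (length(xx) && max(abs(xx - yy) / denom) > tol) {
        i <- which.max(abs(xx - yy) / denom)
        return(sprintf("column `%s` differs beyond tol at row %d: %.12g vs %.12g",
                       nm, i, xx[i], yy[i]))
      }
    } else {
      if (!identical(as.vector(x), as.vector(y))) {
        i <- which(x != y | is.na(x) != is.na(y))[1]
        return(sprintf("column `%s` differs at row %s", nm, i))
      }
    }
  }
  TRUE
}
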
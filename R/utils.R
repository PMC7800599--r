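# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state, so seeded samplers leave no global trace.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  force(code)
}

# Format a double so that it survives a text round trip exactly ("%.17g" is
# lossless for IEEE doubles; %g drops trailing zeros so simple values print
# cleanly).
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a result table as TSV with a commented parameter header
#'
#' All pipeline result tables are written in this dialect: `#`-prefixed
#' `key=value` header lines recording the software version and the parameters
#' that produced the table, then a tab-separated table with a column header.
#'
#' @param df A data.frame.
#' @param path Output file path.
#' @param params Named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# promoterscope version=%s", as.character(packageVersion("promoterscope"))), con)
  for (k in names(params)) {
    writeLines(sprintf("# %s=%s", k, paste(format(params[[k]], trim = TRUE), collapse = ",")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#'
#' @param path File path.
#' @return A data.frame (header comment lines are skipped).
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# The four genome categories, in annotation priority order (highest first,
# INTERGENIC is the fallback).
CATEGORIES <- c("TSS", "TES", "GENE_BODY", "INTERGENIC")

check_count <- function(n, what = "n") {
  if (length(n) != 1 || is.na(n) || n < 0 || n != floor(n))
    stopf("%s must be a single non-negative integer", what)
  as.integer(n)
}
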
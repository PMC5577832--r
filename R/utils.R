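# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so no exported function mutates global RNG state.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonicalise a gene annotation: split on ";", trim, uppercase, dedupe, sort.
# Returns "" for no genes. Vectorised.
normalize_genes <- function(x) {
  vapply(x, function(g) {
    if (is.na(g) || !nzchar(trimws(g)) || trimws(g) %in% c("-", "–", "—", ".")) {
      return("")
    }
    parts <- toupper(trimws(strsplit(g, ";", fixed = TRUE)[[1]]))
    parts <- sort(unique(parts[nzchar(parts)]))
    paste(parts, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

# Split a ";"-joined gene string into a character vector (possibly empty).
split_genes <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

#' Write a result table as TSV
#'
#' Plain TSV writer used for every result table the pipeline emits: tab
#' separated, no quoting, no row names, `NA` for missing.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV result table
#'
#' Inverse of [write_table()]; strings are never converted to factors.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
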
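#' @keywords internal
"_PACKAGE"

# miRNA identifiers are matched case-insensitively after trimming; the
# canonical form stored everywhere is the trimmed, lower-cased spelling.
canon_mirna <- function(x) tolower(trimws(as.character(x)))

canon_mim <- function(x) trimws(as.character(x))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Read a TSV file into a list of character field vectors, skipping blank
# lines and '#' comments, remembering the original line number of each row.
# `file()` decompresses gzip transparently, so .tsv and .tsv.gz both work.
read_tsv_rows <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  con <- file(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(
    fields = strsplit(lines[keep], "\t", fixed = TRUE),
    lineno = lineno[keep]
  )
}

# Parse a character vector as numbers, NA on failure (no warning noise).
parse_num <- function(x) suppressWarnings(as.numeric(x))

stop_io <- function(path, lineno, msg) {
  stop(sprintf("%s, line %d: %s", path, lineno, msg), call. = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
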
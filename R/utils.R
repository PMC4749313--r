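#' Round half away from zero
#'
#' Rounds to the nearest whole number with ties (x.5) going away from zero,
#' the everyday rounding rule applied to raw diploid copy-number calls
#' (so 7.5 becomes 8, -7.5 becomes -8). Idempotent on integers.
#'
#' @param x numeric vector.
#' @return numeric vector of whole numbers.
#' @examples
#' round_half_away(c(10.6, 7.5, 7.49, 11))
#' @export
round_half_away <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of their config.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Detect the field separator of a delimited text file from its header line:
# tab wins if present, otherwise comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("file is empty: ", path)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# Read a comma- or tab-delimited UTF-8 table with a header row.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8", comment.char = "")
}

# Write a table in the same dialect read_delim_auto() accepts.
write_delim_auto <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Case-insensitive, whitespace-trimmed breed key used for all breed matching.
breed_key <- function(x) tolower(trimws(as.character(x)))
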
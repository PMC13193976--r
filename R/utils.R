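# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a stream label
#'
#' All generators in the package draw their randomness from named child
#' streams of a single integer seed, so that each pipeline stage can be
#' regenerated independently and reproducibly. The derivation is a small
#' LCG-style mix of the master seed with an FNV-1a hash of the label; the
#' result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param stream character label of the stream (e.g. `"corpus"`).
#' @return an integer seed for `set.seed()`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- fnv1a(stream)
  # keep all arithmetic in doubles below 2^53, reduce mod 2^31 - 1
  m <- 2147483647
  s <- (abs(seed) %% m)
  x <- (s * 48271) %% m
  x <- (x + h) %% m
  as.integer(x)
}

# FNV-1a 32-bit hash of a string, folded into [0, 2^31 - 1).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Canonical unordered pair key "a||b" with a < b lexicographically (C locale).
pair_key <- function(a, b) {
  swap <- cmp_gt(a, b)
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\u0001")
}

# Locale-independent string comparison (C collation via sort method).
cmp_gt <- function(a, b) {
  # TRUE where a > b in C locale
  mapply(function(x, y) {
    r <- sort(c(x, y), method = "radix")
    !identical(r[1], x) && x != y
  }, a, b, USE.NAMES = FALSE)
}

sort_c <- function(x) sort(x, method = "radix")

# Deterministic CSV writer: fixed field order, no row names, "." decimal,
# UTF-8, LF line endings -- identical inputs give byte-identical files.
write_csv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, fileEncoding = "UTF-8",
                   eol = "\n", quote = TRUE)
  invisible(path)
}

read_csv_stable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

# JSON-Lines helpers (one object per line, UTF-8).
write_jsonl <- function(objs, path) {
  lines <- vapply(objs, function(o) {
    as.character(jsonlite::toJSON(o, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

# Minimal XML escaping for GraphML export.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}
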
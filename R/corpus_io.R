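# Reading, normalizing, deduplicating and writing bibliographic records.
#
# A corpus is a plain data.frame with one row per publication and columns
#   record_id   opaque identifier (DOI, WoS UT, or PMID)
#   title       character
#   abstract    character (may be "")
#   year        integer calendar year
#   source_db   one of "wos", "pubmed", "synthetic"
#   keywords    list-column of character vectors (raw keyword strings)
#   times_cited non-negative integer (per-record citation count; sums to TGCS)
#   countries   list-column of character vectors (country names)
#   journal     character

SOURCE_DBS <- c("wos", "pubmed", "synthetic")

# Country aliases applied when extracting affiliations, matching common
# bibliometric practice (WoS prints "Peoples R China", UK home nations, etc.).
COUNTRY_ALIASES <- c(
  "Peoples R China" = "China",
  "P R China"       = "China",
  "England"         = "United Kingdom",
  "Scotland"        = "United Kingdom",
  "Wales"           = "United Kingdom",
  "North Ireland"   = "United Kingdom",
  "USA"             = "United States",
  "U S A"           = "United States"
)

#' Construct a bibliographic corpus data frame
#'
#' Low-level constructor used by the parsers and the synthetic generator;
#' validates the record invariants (non-empty ids, year range, non-negative
#' citation counts, no empty keyword strings).
#'
#' @param record_id,title,abstract,year,source_db,times_cited,journal
#'   per-record scalar fields (vectors of equal length).
#' @param keywords,countries lists of character vectors, one per record.
#' @return a `biblio_corpus` data.frame.
#' @export
biblio_corpus <- function(record_id, title = "", abstract = "", year,
                          source_db = "synthetic", keywords = list(),
                          times_cited = 0L, countries = list(),
                          journal = "") {
  n <- length(record_id)
  recycle <- function(x) if (length(x) == n) x else rep(x, length.out = n)
  keywords <- if (length(keywords) == 0L) rep(list(character(0)), n) else keywords
  countries <- if (length(countries) == 0L) rep(list(character(0)), n) else countries
  df <- data.frame(record_id = as.character(record_id),
                   title = as.character(recycle(title)),
                   abstract = as.character(recycle(abstract)),
                   year = as.integer(year),
                   source_db = as.character(recycle(source_db)),
                   times_cited = as.integer(recycle(times_cited)),
                   journal = as.character(recycle(journal)),
                   stringsAsFactors = FALSE)
  df$keywords <- lapply(keywords, function(k) {
    k <- trimws(as.character(k))
    k[nzchar(k)]
  })
  df$countries <- lapply(countries, function(k) unique(trimws(as.character(k))))
  validate_corpus(df)
  class(df) <- c("biblio_corpus", "data.frame")
  df
}

validate_corpus <- function(df) {
  if (any(!nzchar(df$record_id))) stop("record_id must be non-empty")
  bad_year <- !is.na(df$year) & (df$year < 1900L | df$year > 2100L)
  if (any(bad_year)) stop("year outside [1900, 2100]: ",
                          paste(df$record_id[bad_year], collapse = ", "))
  if (any(df$times_cited < 0L, na.rm = TRUE)) stop("times_cited must be >= 0")
  if (any(!df$source_db %in% SOURCE_DBS))
    stop("source_db must be one of ", paste(SOURCE_DBS, collapse = ", "))
  invisible(df)
}

empty_corpus <- function() {
  biblio_corpus(record_id = character(0), year = integer(0))
}

apply_country_alias <- function(x) {
  hit <- match(x, names(COUNTRY_ALIASES))
  x[!is.na(hit)] <- COUNTRY_ALIASES[hit[!is.na(hit)]]
  x
}

#' Parse a Web of Science tab-delimited export
#'
#' Expects the tab-delimited dialect with a header row naming field-tag
#' columns. Required columns are `DE` (author keywords) and `PY` (publication
#' year); `UT`, `TI`, `AB`, `ID`, `TC`, `SO`, `C1` are used when present.
#' Keywords are the `DE` entries split on `";"`; Keywords Plus (`ID`) terms
#' are appended only when `keywords_plus = TRUE`. Countries are taken as the
#' last comma-separated token of each `C1` address, passed through a small
#' alias table and deduplicated per record. Rows whose `PY` does not parse as
#' a year are skipped with a warning.
#'
#' @param text character scalar (file content) or vector of lines.
#' @param keywords_plus append Keywords Plus terms to author keywords?
#' @return a `biblio_corpus` data.frame with `source_db = "wos"`.
#' @export
parse_wos_export <- function(text, keywords_plus = FALSE) {
  lines <- split_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("WoS export is empty (no header row)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  required <- c("DE", "PY")
  missing <- setdiff(required, header)
  if (length(missing) > 0L)
    stop("WoS export header is missing required column: ", missing[[1]])
  if (length(lines) == 1L) return(empty_corpus())

  col <- function(fields, tag) {
    i <- match(tag, header)
    if (is.na(i) || i > length(fields)) "" else trimws(fields[[i]])
  }
  out <- vector("list", length(lines) - 1L)
  kept <- 0L
  for (li in seq.int(2L, length(lines))) {
    fields <- strsplit(lines[[li]], "\t", fixed = TRUE)[[1]]
    py <- col(fields, "PY")
    year <- suppressWarnings(as.integer(py))
    if (is.na(year)) {
      warning("skipping WoS row ", li, ": unparseable PY ", dQuote(py),
              call. = FALSE)
      next
    }
    kw <- split_semicolons(col(fields, "DE"))
    if (keywords_plus) kw <- c(kw, split_semicolons(col(fields, "ID")))
    tc <- suppressWarnings(as.integer(col(fields, "TC")))
    if (is.na(tc)) tc <- 0L
    countries <- parse_c1_countries(col(fields, "C1"))
    id <- col(fields, "UT")
    if (!nzchar(id)) id <- paste0("WOS-ROW-", li - 1L)
    kept <- kept + 1L
    out[[kept]] <- list(record_id = id, title = col(fields, "TI"),
                        abstract = col(fields, "AB"), year = year,
                        times_cited = tc, journal = col(fields, "SO"),
                        keywords = kw, countries = countries)
  }
  out <- out[seq_len(kept)]
  if (kept == 0L) return(empty_corpus())
  biblio_corpus(record_id = vapply(out, `[[`, "", "record_id"),
                title = vapply(out, `[[`, "", "title"),
                abstract = vapply(out, `[[`, "", "abstract"),
                year = vapply(out, `[[`, 0L, "year"),
                source_db = "wos",
                keywords = lapply(out, `[[`, "keywords"),
                times_cited = vapply(out, `[[`, 0L, "times_cited"),
                countries = lapply(out, `[[`, "countries"),
                journal = vapply(out, `[[`, "", "journal"))
}

split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\r?\n")[[1]]
  } else {
    sub("\r$", "", text)
  }
}

split_semicolons <- function(x) {
  if (!nzchar(x)) return(character(0))
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

# C1 addresses are ";"-separated; country = last comma-separated token,
# with trailing periods stripped ("... Guangzhou, Peoples R China.").
parse_c1_countries <- function(x) {
  if (!nzchar(x)) return(character(0))
  addrs <- split_semicolons(x)
  countries <- vapply(addrs, function(a) {
    toks <- trimws(strsplit(a, ",", fixed = TRUE)[[1]])
    if (length(toks) == 0L) return("")
    sub("\\.+$", "", toks[[length(toks)]])
  }, character(1), USE.NAMES = FALSE)
  unique(apply_country_alias(countries[nzchar(countries)]))
}

#' Parse a PubMed MEDLINE (nbib) export
#'
#' Records are separated by blank lines; each line is `TAG - value`, and
#' continuation lines begin with whitespace and are joined to the previous
#' value. Keywords are the union of `OT` (author keywords) and `MH` (MeSH
#' headings, with any `/qualifier` suffix stripped); the year is the first
#' four-digit token of `DP`. MEDLINE carries no citation counts, so
#' `times_cited` is 0. Records lacking a `PMID` are skipped with a warning.
#'
#' @param text character scalar or vector of lines.
#' @return a `biblio_corpus` data.frame with `source_db = "pubmed"`.
#' @export
parse_pubmed_medline <- function(text) {
  lines <- split_lines(text)
  # split into record blocks on blank lines
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank & !c(FALSE, blank[-length(blank)]))
  blocks <- split(lines[!blank], grp[!blank])
  recs <- lapply(blocks, parse_medline_block)
  keep <- !vapply(recs, is.null, TRUE)
  dropped <- sum(!keep)
  if (dropped > 0L)
    warning("skipped ", dropped, " MEDLINE record(s) lacking PMID",
            call. = FALSE)
  recs <- recs[keep]
  if (length(recs) == 0L) return(empty_corpus())
  biblio_corpus(record_id = vapply(recs, `[[`, "", "record_id"),
                title = vapply(recs, `[[`, "", "title"),
                abstract = vapply(recs, `[[`, "", "abstract"),
                year = vapply(recs, `[[`, 0L, "year"),
                source_db = "pubmed",
                keywords = lapply(recs, `[[`, "keywords"),
                times_cited = 0L,
                countries = rep(list(character(0)), length(recs)),
                journal = vapply(recs, `[[`, "", "journal"))
}

parse_medline_block <- function(lines) {
  tags <- character(0)
  vals <- character(0)
  for (ln in lines) {
    if (grepl("^\\s", ln) && length(vals) > 0L) {
      vals[length(vals)] <- paste(vals[length(vals)], trimws(ln))
    } else if (grepl("^[A-Z0-9]{1,4}\\s*-", ln)) {
      tag <- trimws(sub("-.*$", "", ln))
      val <- trimws(sub("^[A-Z0-9]{1,4}\\s*-\\s?", "", ln))
      tags <- c(tags, tag)
      vals <- c(vals, val)
    }
  }
  get1 <- function(tag) {
    v <- vals[tags == tag]
    if (length(v) == 0L) "" else v[[1]]
  }
  pmid <- get1("PMID")
  if (!nzchar(pmid)) return(NULL)
  ot <- vals[tags == "OT"]
  mh <- sub("/.*$", "", vals[tags == "MH"])  # strip qualifier suffixes
  kw <- unique(trimws(c(ot, mh)))
  kw <- kw[nzchar(kw)]
  dp <- get1("DP")
  ym <- regmatches(dp, regexpr("\\b\\d{4}\\b", dp))
  year <- if (length(ym) == 1L) as.integer(ym) else NA_integer_
  list(record_id = pmid, title = get1("TI"), abstract = get1("AB"),
       year = year, keywords = kw, journal = get1("SO"))
}

#' Deduplicate a corpus across databases
#'
#' Records sharing a DOI are merged; otherwise records sharing a normalized
#' title (case-folded, punctuation stripped) and year are merged. A merged
#' record keeps the union of keywords and countries, the maximum
#' `times_cited`, and the WoS `record_id` when one of the duplicates is a
#' WoS record (WoS ids carry the citation counts that feed TGCS). Output
#' order is the order of first occurrence; the operation is idempotent.
#'
#' @param records a `biblio_corpus`.
#' @param doi optional character vector of DOIs aligned with `records`
#'   (`NA`/"" where unknown); by default `record_id` entries that look like
#'   DOIs (`10.xxxx/...`) are used.
#' @return the deduplicated `biblio_corpus`.
#' @export
dedupe_records <- function(records, doi = NULL) {
  n <- nrow(records)
  if (n == 0L) return(records)
  if (is.null(doi)) {
    doi <- ifelse(grepl("^10\\.\\d{4,}/", records$record_id),
                  tolower(records$record_id), NA_character_)
  } else {
    doi <- ifelse(is.na(doi) | !nzchar(doi), NA_character_, tolower(doi))
  }
  title_key <- paste(normalize_title(records$title), records$year, sep = "|")
  key <- ifelse(!is.na(doi), paste0("doi:", doi), paste0("ty:", title_key))
  first <- !duplicated(key)
  groups <- split(seq_len(n), key)
  merged <- lapply(groups, function(ix) merge_group(records, ix))
  ord <- order(match(names(groups), key[first]))
  merged <- merged[ord]
  biblio_corpus(record_id = vapply(merged, `[[`, "", "record_id"),
                title = vapply(merged, `[[`, "", "title"),
                abstract = vapply(merged, `[[`, "", "abstract"),
                year = vapply(merged, function(m) as.integer(m$year), 0L),
                source_db = vapply(merged, `[[`, "", "source_db"),
                keywords = lapply(merged, `[[`, "keywords"),
                times_cited = vapply(merged, function(m) as.integer(m$times_cited), 0L),
                countries = lapply(merged, `[[`, "countries"),
                journal = vapply(merged, `[[`, "", "journal"))
}

normalize_title <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", "", x)
  gsub("\\s+", " ", trimws(x))
}

merge_group <- function(records, ix) {
  sub <- records[ix, , drop = FALSE]
  wos <- which(sub$source_db == "wos")
  lead <- if (length(wos) > 0L) wos[[1]] else 1L
  list(record_id = sub$record_id[[lead]],
       title = sub$title[[1]],
       abstract = sub$abstract[[which.max(nchar(sub$abstract))]],
       year = sub$year[[1]],
       source_db = sub$source_db[[lead]],
       times_cited = max(sub$times_cited),
       journal = sub$journal[[lead]],
       keywords = unique(unlist(sub$keywords, use.names = FALSE)) %||% character(0),
       countries = unique(unlist(sub$countries, use.names = FALSE)) %||% character(0))
}

#' Write / read a corpus as JSON Lines
#'
#' One JSON object per record, UTF-8, with fields exactly matching the
#' corpus columns. `read_records_jsonl(write_records_jsonl(x))` reproduces
#' the corpus field-for-field.
#'
#' @param records a `biblio_corpus`.
#' @param path file path.
#' @return `write_records_jsonl` returns `path` invisibly;
#'   `read_records_jsonl` returns a `biblio_corpus`.
#' @export
write_records_jsonl <- function(records, path) {
  objs <- lapply(seq_len(nrow(records)), function(i) {
    list(record_id = records$record_id[[i]],
         title = records$title[[i]],
         abstract = records$abstract[[i]],
         year = records$year[[i]],
         source_db = records$source_db[[i]],
         keywords = as.list(records$keywords[[i]]),
         times_cited = records$times_cited[[i]],
         countries = as.list(records$countries[[i]]),
         journal = records$journal[[i]])
  })
  write_jsonl(objs, path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  objs <- read_jsonl(path)
  if (length(objs) == 0L) return(empty_corpus())
  chr0 <- function(o, f) as.character(unlist(o[[f]]) %||% character(0))
  biblio_corpus(record_id = vapply(objs, function(o) o$record_id, ""),
                title = vapply(objs, function(o) o$title %||% "", ""),
                abstract = vapply(objs, function(o) o$abstract %||% "", ""),
                year = vapply(objs, function(o) as.integer(o$year), 0L),
                source_db = vapply(objs, function(o) o$source_db %||% "synthetic", ""),
                keywords = lapply(objs, chr0, "keywords"),
                times_cited = vapply(objs, function(o) as.integer(o$times_cited %||% 0L), 0L),
                countries = lapply(objs, chr0, "countries"),
                journal = vapply(objs, function(o) o$journal %||% "", ""))
}
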
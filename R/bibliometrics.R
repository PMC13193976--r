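# Descriptive corpus statistics: annual output trend, country aggregation
# with TGCS (total global citation score = summed per-record citations),
# and rank correlation against an external country indicator such as HDI.

#' Annual publication trend with OLS fit
#'
#' Counts publications per year (interior years with no publications are
#' filled with zero counts) and fits ordinary least squares of count on
#' calendar year: the slope is publications per year, the intercept the
#' extrapolated count at year 0 -- the usual "Y = a x + b" growth line of
#' bibliometric trend plots.
#'
#' @param records a `biblio_corpus` spanning at least two distinct years.
#' @return list with `slope`, `intercept`, and `yearly` =
#'   data.frame(year, count).
#' @export
annual_trend <- function(records) {
  years <- records$year[!is.na(records$year)]
  if (length(unique(years)) < 2L)
    stop("annual trend needs at least 2 distinct publication years")
  rng <- range(years)
  grid <- seq.int(rng[1], rng[2])
  counts <- vapply(grid, function(y) sum(years == y), 0L)
  fit <- stats::lm(counts ~ grid)
  co <- stats::coef(fit)
  list(slope = unname(co[["grid"]]),
       intercept = unname(co[["(Intercept)"]]),
       yearly = data.frame(year = grid, count = counts))
}

#' Per-country publication counts and TGCS
#'
#' Whole counting: a record contributes one publication and its full
#' `times_cited` to *every* country it lists (so country sums can exceed
#' the record count -- the standard reading of country tables in
#' bibliometric reports). HDI values are joined by country name through
#' the same alias table used at parse time; countries absent from the HDI
#' table get `NA`, not 0.
#'
#' @param records a `biblio_corpus`.
#' @param hdi_table optional data.frame(country, hdi).
#' @return data.frame(country, recs, tgcs, hdi) sorted by descending recs.
#' @export
country_stats <- function(records, hdi_table = NULL) {
  pairs <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    cs <- records$countries[[i]]
    if (length(cs) == 0L) return(NULL)
    data.frame(country = apply_country_alias(cs),
               tc = records$times_cited[[i]], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    return(data.frame(country = character(0), recs = integer(0),
                      tgcs = integer(0), hdi = numeric(0)))
  recs <- tapply(rep(1L, nrow(pairs)), pairs$country, sum)
  tgcs <- tapply(pairs$tc, pairs$country, sum)
  df <- data.frame(country = names(recs),
                   recs = as.integer(recs),
                   tgcs = as.integer(tgcs),
                   stringsAsFactors = FALSE)
  if (!is.null(hdi_table)) {
    key <- apply_country_alias(hdi_table$country)
    df$hdi <- hdi_table$hdi[match(df$country, key)]
  } else {
    df$hdi <- NA_real_
  }
  df <- df[order(-df$recs, df$country, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#' Invariant under strictly monotone transforms of either vector. A
#' constant vector makes the coefficient undefined; `NA` is returned with
#' a warning.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must be paired (equal length)")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("spearman_rho undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Read an HDI (or any country-indicator) table
#'
#' CSV with header `country,hdi`.
#'
#' @param path file path.
#' @return data.frame(country, hdi).
#' @export
read_hdi_csv <- function(path) {
  df <- read_csv_stable(path)
  stopifnot(all(c("country", "hdi") %in% names(df)))
  df
}
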
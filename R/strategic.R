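# Callon strategic diagram: per-theme centrality/density and quadrants.
#
# For a theme (community) C in the co-occurrence network:
#   density    = 100 * (sum of weights of edges with both ends in C) / |C|
#                -- internal cohesion per member (Y axis);
#   centrality = 10 * (sum of weights of edges with exactly one end in C)
#                -- total link strength to other themes (X axis).
# These are the classic Callon conventions used by strategic-diagram tools.
# Quadrants: with split points on each axis ("high" meaning >= split),
#   Q1 motor        high centrality, high density
#   Q2 niche        low  centrality, high density
#   Q3 declining    low  centrality, low  density
#   Q4 basic/future high centrality, low  density  <- well-connected but
#                   not yet internally developed research directions.

#' Per-theme Callon centrality and density
#'
#' A singleton theme has density 0 (reported, not an error). The theme
#' label is its member with the highest occurrence count (ties broken
#' lexicographically).
#'
#' @param net a `cooc_network`.
#' @param partition a `community_partition` or a named assignment vector
#'   defined on the network's nodes.
#' @param min_size drop themes with fewer members than this before
#'   returning (default 1 keeps everything; strategic-diagram runs on real
#'   corpora typically use 3 to suppress noise themes).
#' @return data.frame(theme, label, size, centrality, density) plus a
#'   `members` list-column.
#' @export
theme_metrics <- function(net, partition, min_size = 1L) {
  assignment <- if (inherits(partition, "community_partition"))
    partition$assignment else partition
  nm <- names(net$nodes)
  miss <- setdiff(nm, names(assignment))
  if (length(miss) > 0L)
    stop("partition does not cover node: ", sort_c(miss)[[1]])
  comm <- assignment[nm]
  ids <- sort(unique(as.integer(comm)))
  ef <- comm[net$edges$from]; et <- comm[net$edges$to]
  w <- net$edges$weight
  rows <- lapply(ids, function(id) {
    inside <- nm[comm == id]
    internal <- sum(w[ef == id & et == id])
    external <- sum(w[xor(ef == id, et == id)])
    counts <- net$nodes[inside]
    lab <- inside[order(-as.numeric(counts), inside, method = "radix")][[1]]
    list(theme = id, label = lab, size = length(inside),
         centrality = 10 * external,
         density = 100 * internal / length(inside),
         members = inside)
  })
  df <- data.frame(theme = vapply(rows, `[[`, 0L, "theme"),
                   label = vapply(rows, `[[`, "", "label"),
                   size = vapply(rows, `[[`, 0L, "size"),
                   centrality = vapply(rows, `[[`, 0, "centrality"),
                   density = vapply(rows, `[[`, 0, "density"),
                   stringsAsFactors = FALSE)
  df$members <- lapply(rows, `[[`, "members")
  if (any(df$size == 1L))
    message("theme_metrics: ", sum(df$size == 1L),
            " singleton theme(s) have density 0")
  df[df$size >= min_size, , drop = FALSE]
}

#' Classify themes into strategic-diagram quadrants
#'
#' Split points are the median (default) or mean of the theme centralities
#' and densities; "high" means greater than or equal to the split. The
#' assignment is invariant under a common positive rescaling of either
#' axis.
#'
#' @param metrics output of [theme_metrics()].
#' @param split `"median"` or `"mean"`.
#' @return `metrics` with a `quadrant` column (`"Q1"`..`"Q4"`) and split
#'   points stored in attributes `split_x` (centrality) and `split_y`
#'   (density).
#' @export
classify_quadrants <- function(metrics, split = c("median", "mean")) {
  split <- match.arg(split)
  if (nrow(metrics) < 1L) stop("need at least one theme")
  f <- if (split == "median") stats::median else mean
  sx <- f(metrics$centrality)
  sy <- f(metrics$density)
  high_c <- metrics$centrality >= sx
  high_d <- metrics$density >= sy
  metrics$quadrant <- ifelse(high_c & high_d, "Q1",
                      ifelse(!high_c & high_d, "Q2",
                      ifelse(!high_c & !high_d, "Q3", "Q4")))
  attr(metrics, "split_x") <- sx
  attr(metrics, "split_y") <- sy
  metrics
}

#' Write theme metrics as CSV
#'
#' Columns `theme,label,size,centrality,density,quadrant` (quadrant empty
#' when not yet classified).
#'
#' @param metrics output of [theme_metrics()] / [classify_quadrants()].
#' @param path file path.
#' @export
write_theme_csv <- function(metrics, path) {
  df <- data.frame(theme = metrics$theme, label = metrics$label,
                   size = metrics$size,
                   centrality = metrics$centrality,
                   density = metrics$density,
                   quadrant = if ("quadrant" %in% names(metrics))
                     metrics$quadrant else "",
                   stringsAsFactors = FALSE)
  write_csv_stable(df, path)
}
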
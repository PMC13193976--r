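# Weighted undirected keyword co-occurrence networks.
#
# A `cooc_network` is a list with
#   nodes : named integer vector, canonical keyword -> occurrence count
#           (number of records in which the keyword appears)
#   edges : data.frame(from, to, weight) with from < to in C collation,
#           weight = number of records containing both endpoints
# plus convenience counts N (nodes) and E (distinct edges).
# Everything downstream (Walktrap, Callon metrics, node centralities)
# consumes this container.

new_cooc_network <- function(nodes, edges) {
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 N = length(nodes), E = nrow(edges)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("cooc_network:", x$N, "nodes,", x$E, "edges, total weight",
      sum(x$edges$weight), "\n")
  invisible(x)
}

#' Build a keyword co-occurrence network from a corpus
#'
#' Each record contributes its set of *unique canonical* keywords; every
#' unordered pair of that set gains +1 co-occurrence weight, and every
#' member gains +1 occurrence count. Raw keywords are passed through the
#' keyword map first (terms the map does not know map to their normalized
#' selves with a warning). The construction is deterministic: node and edge
#' tables are sorted lexicographically.
#'
#' @param records a `biblio_corpus`.
#' @param map a `keyword_map` (optional; `NULL` uses raw keywords as-is).
#' @return a `cooc_network`.
#' @export
build_cooccurrence <- function(records, map = NULL) {
  node_env <- new.env(hash = TRUE, parent = emptyenv())
  edge_env <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(env, key, by = 1L) {
    assign(key, (get0(key, envir = env) %||% 0L) + by, envir = env)
  }
  for (i in seq_len(nrow(records))) {
    kw <- records$keywords[[i]]
    if (length(kw) == 0L) next
    canon <- if (is.null(map)) normalize_term(kw) else map_keywords(map, kw, warn = TRUE)
    canon <- sort_c(unique(canon[nzchar(canon)]))
    for (k in canon) bump(node_env, k)
    nk <- length(canon)
    if (nk >= 2L) {
      for (a in seq_len(nk - 1L)) for (b in seq.int(a + 1L, nk)) {
        bump(edge_env, paste(canon[[a]], canon[[b]], sep = "\u0001"))
      }
    }
  }
  node_names <- sort_c(ls(node_env))
  nodes <- vapply(node_names, get, 0L, envir = node_env)
  ekeys <- sort_c(ls(edge_env))
  if (length(ekeys) > 0L) {
    parts <- strsplit(ekeys, "\u0001", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                        to = vapply(parts, `[[`, "", 2L),
                        weight = vapply(ekeys, get, 0L, envir = edge_env),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  }
  new_cooc_network(nodes, edges)
}

#' Construct a network directly from an edge list
#'
#' Utility for tests and for re-loading exported edge lists. Occurrence
#' counts default to each node's weighted degree (they matter only for
#' theme labels).
#'
#' @param from,to character endpoint vectors.
#' @param weight numeric edge weights (default 1).
#' @param nodes optional named counts to include isolated nodes.
#' @return a `cooc_network`.
#' @export
cooc_from_edges <- function(from, to, weight = 1, nodes = NULL) {
  if (length(weight) == 1L) weight <- rep(weight, length(from))
  if (any(from == to)) stop("self-loops are not allowed")
  swap <- cmp_gt(from, to)
  lo <- ifelse(swap, to, from); hi <- ifelse(swap, from, to)
  key <- paste(lo, hi, sep = "\u0001")
  w <- tapply(weight, key, sum)
  parts <- strsplit(names(w), "\u0001", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      to = vapply(parts, `[[`, "", 2L),
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  nm <- sort_c(unique(c(edges$from, edges$to, names(nodes))))
  counts <- structure(integer(length(nm)), names = nm)
  wd <- tapply(c(edges$weight, edges$weight), c(edges$from, edges$to), sum)
  counts[names(wd)] <- as.integer(round(wd))
  if (!is.null(nodes)) counts[names(nodes)] <- as.integer(nodes)
  new_cooc_network(counts, edges)
}

# Adjacency structures used by the algorithms: index nodes 1..N in the
# order of net$nodes; return neighbor/weight lists.
adjacency_lists <- function(net) {
  nm <- names(net$nodes)
  idx <- seq_along(nm); names(idx) <- nm
  nbr <- vector("list", length(nm))
  wts <- vector("list", length(nm))
  for (i in idx) { nbr[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  if (nrow(net$edges) > 0L) {
    fi <- idx[net$edges$from]; ti <- idx[net$edges$to]
    for (e in seq_len(nrow(net$edges))) {
      a <- fi[[e]]; b <- ti[[e]]; w <- net$edges$weight[[e]]
      nbr[[a]] <- c(nbr[[a]], b); wts[[a]] <- c(wts[[a]], w)
      nbr[[b]] <- c(nbr[[b]], a); wts[[b]] <- c(wts[[b]], w)
    }
  }
  list(names = nm, nbr = nbr, wts = wts)
}

adjacency_matrix <- function(net) {
  nm <- names(net$nodes)
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(net$edges) > 0L) {
    fi <- match(net$edges$from, nm); ti <- match(net$edges$to, nm)
    A[cbind(fi, ti)] <- net$edges$weight
    A[cbind(ti, fi)] <- net$edges$weight
  }
  A
}

cooc_components <- function(net) {
  adj <- adjacency_lists(net)
  n <- length(adj$names)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s; comp[s] <- cur
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      nb <- adj$nbr[[v]][comp[adj$nbr[[v]]] == 0L]
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  split(adj$names, comp)
}

#' Retain the giant component of a network
#'
#' Returns the subgraph induced by the largest connected component
#' (isolated nodes and minor components are dropped; the removed node count
#' is reported as a message). A tie between equal-size components is broken
#' in favor of the component containing the lexicographically smallest node
#' label.
#'
#' @param net a `cooc_network`.
#' @return the induced `cooc_network`.
#' @export
giant_component <- function(net) {
  if (net$N == 0L) return(net)
  comps <- cooc_components(net)
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(comps[best], function(x) sort_c(x)[[1]], "")
    best <- best[order(mins, method = "radix")[[1]]]
  } else best <- best[[1]]
  keep <- comps[[best]]
  removed <- net$N - length(keep)
  if (removed > 0L)
    message("giant_component: removed ", removed, " node(s)")
  induced_subgraph_cooc(net, keep)
}

induced_subgraph_cooc <- function(net, keep) {
  nodes <- net$nodes[names(net$nodes) %in% keep]
  e <- net$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  new_cooc_network(nodes, e)
}

#' Graph density
#'
#' `2E / (N (N - 1))` for an undirected simple graph: the fraction of
#' realized node pairs, ignoring edge weights.
#'
#' @param net a `cooc_network` with at least two nodes.
#' @return density in `[0, 1]`.
#' @export
graph_density <- function(net) {
  if (net$N < 2L) stop("density requires at least 2 nodes")
  2 * net$E / (net$N * (net$N - 1))
}

#' Node centralities of a connected network
#'
#' Computes the four classical normalized centralities on the (giant
#' component of a) co-occurrence or knowledge graph:
#'
#' * degree: `deg(v) / (N - 1)` (always the unweighted connection count);
#' * betweenness: Brandes' exact algorithm, shortest-path ties split
#'   proportionally, normalized by `(N - 1)(N - 2) / 2`;
#' * closeness: `(N - 1) / sum_u dist(v, u)`;
#' * eigenvector: power iteration (identity-shifted adjacency for
#'   convergence on bipartite graphs; same principal eigenvector), all-ones
#'   start, L2 normalization each step, tolerance 1e-10, at most 1000
#'   iterations, final vector scaled to maximum entry 1.
#'
#' With `weighted = TRUE`, betweenness and closeness measure shortest paths
#' under edge length `1 / weight` (strong co-occurrence = short distance)
#' and the eigenvector uses the weighted adjacency; degree stays unweighted.
#'
#' @param net a connected `cooc_network` with N >= 2.
#' @param weighted use edge weights for paths / eigenvector?
#' @param metrics which centralities to compute; graphs made of several
#'   near-identical weakly coupled clusters have an almost-degenerate
#'   leading eigenpair, and dropping `"eigenvector"` avoids the (correctly
#'   reported) power-iteration stall there.
#' @return data.frame(node, degree_c, betweenness_c, closeness_c,
#'   eigenvector_c), all in `[0, 1]` (requested columns only).
#' @export
node_centralities <- function(net, weighted = FALSE,
                              metrics = c("degree", "betweenness",
                                          "closeness", "eigenvector")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (net$N < 2L) stop("centralities require at least 2 nodes")
  if (length(cooc_components(net)) > 1L)
    stop("network is disconnected; run giant_component() first")
  adj <- adjacency_lists(net)
  n <- net$N
  out <- data.frame(node = adj$names, stringsAsFactors = FALSE,
                    row.names = NULL)
  if ("degree" %in% metrics)
    out$degree_c <- lengths(adj$nbr) / (n - 1)
  if ("betweenness" %in% metrics) {
    bw <- brandes_betweenness(adj, weighted = weighted)
    out$betweenness_c <- if (n > 2L) bw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  }
  if ("closeness" %in% metrics) {
    dist <- all_pairs_dist(adj, weighted = weighted)
    out$closeness_c <- (n - 1) / rowSums(dist)
  }
  if ("eigenvector" %in% metrics)
    out$eigenvector_c <- eigenvector_power(net, weighted = weighted)
  out
}

# Brandes (2001) exact betweenness; returns RAW unordered-pair counts
# (sum over pairs s<t of the fraction of s-t shortest paths through v).
brandes_betweenness <- function(adj, weighted = FALSE) {
  n <- length(adj$names)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    sp <- sssp(adj, s, weighted)
    delta <- numeric(n)
    for (w in rev(sp$order)) {
      for (v in sp$pred[[w]]) {
        delta[v] <- delta[v] + sp$sigma[v] / sp$sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2  # each unordered pair visited from both endpoints
}

# Single-source shortest paths with path counts and predecessor lists.
# Unweighted: BFS. Weighted: Dijkstra over lengths 1/weight.
sssp <- function(adj, s, weighted) {
  n <- length(adj$names)
  sigma <- numeric(n); sigma[s] <- 1
  dist <- rep(Inf, n); dist[s] <- 0
  pred <- vector("list", n)
  order_out <- integer(0)
  if (!weighted) {
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      order_out <- c(order_out, v)
      for (w in adj$nbr[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
  } else {
    done <- logical(n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0L) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      order_out <- c(order_out, v)
      nb <- adj$nbr[[v]]; len <- 1 / adj$wts[[v]]
      for (k in seq_along(nb)) {
        w <- nb[[k]]; d <- dist[v] + len[[k]]
        if (d < dist[w] - 1e-12) {
          dist[w] <- d; sigma[w] <- sigma[v]; pred[[w]] <- v
        } else if (abs(d - dist[w]) <= 1e-12) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
  }
  list(sigma = sigma, dist = dist, pred = pred, order = order_out)
}

all_pairs_dist <- function(adj, weighted = FALSE) {
  n <- length(adj$names)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) D[s, ] <- sssp(adj, s, weighted)$dist
  D
}

eigenvector_power <- function(net, weighted = FALSE, tol = 1e-10,
                              max_iter = 1000L) {
  A <- adjacency_matrix(net)
  if (!weighted) A[A > 0] <- 1
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    # identity shift keeps iteration convergent on bipartite graphs and
    # leaves the principal eigenvector of a connected graph unchanged
    xn <- A %*% x + x
    xn <- xn / sqrt(sum(xn^2))
    if (sqrt(sum((xn - x)^2)) < tol) {
      return(as.numeric(xn) / max(xn))
    }
    x <- xn
  }
  stop("eigenvector power iteration did not converge in ", max_iter,
       " iterations")
}

#' Export a network as a weighted edge-list CSV
#'
#' Columns `source,target,weight`, sorted; consumable by VOSviewer- or
#' Cytoscape-class tools and by [read_edgelist_csv()].
#'
#' @param net a `cooc_network`.
#' @param path file path.
#' @export
write_edgelist_csv <- function(net, path) {
  df <- data.frame(source = net$edges$from, target = net$edges$to,
                   weight = net$edges$weight, stringsAsFactors = FALSE)
  write_csv_stable(df, path)
}

#' @rdname write_edgelist_csv
#' @export
read_edgelist_csv <- function(path) {
  df <- read_csv_stable(path)
  cooc_from_edges(df$source, df$target, df$weight)
}

#' Export a network as GraphML
#'
#' Minimal GraphML with node occurrence counts and edge weights; readable
#' by Cytoscape, Gephi, and igraph.
#'
#' @param net a `cooc_network`.
#' @param path file path.
#' @export
write_graphml <- function(net, path) {
  nm <- names(net$nodes)
  id <- seq_along(nm) - 1L; names(id) <- nm
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="count" attr.type="int"/>',
    '  <key id="d2" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="n%d"><data key="d0">%s</data><data key="d1">%d</data></node>',
            id, xml_escape(nm), as.integer(net$nodes)),
    if (nrow(net$edges) > 0L)
      sprintf('    <edge source="n%d" target="n%d"><data key="d2">%s</data></edge>',
              id[net$edges$from], id[net$edges$to],
              format(net$edges$weight, trim = TRUE)),
    '  </graph>',
    '</graphml>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
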
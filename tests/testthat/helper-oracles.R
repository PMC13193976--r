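# Independent oracles used to check the graph algorithms: exhaustive
# shortest-path enumeration for betweenness, exhaustive set-partition
# search for modularity, the adjusted Rand index, and small random-graph
# generators. Everything here is deliberately brute force and shares no
# code with the implementations under test.

# All shortest paths s -> t as lists of node indices, by recursive
# backtracking over BFS distances.
oracle_all_shortest_paths <- function(nbr, s, t) {
  n <- length(nbr)
  dist <- rep(Inf, n); dist[s] <- 0
  queue <- s
  while (length(queue) > 0L) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in nbr[[v]]) if (is.infinite(dist[w])) {
      dist[w] <- dist[v] + 1; queue <- c(queue, w)
    }
  }
  if (is.infinite(dist[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- nbr[[v]][dist[nbr[[v]]] == dist[v] - 1]
    out <- list()
    for (p in preds) for (path in walk(p))
      out[[length(out) + 1L]] <- c(path, v)
    out
  }
  walk(t)
}

# Raw (unnormalized, unordered-pair) betweenness by explicit enumeration.
oracle_betweenness <- function(net) {
  nm <- names(net$nodes)
  n <- length(nm)
  nbr <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(net$edges))) {
    a <- match(net$edges$from[[e]], nm); b <- match(net$edges$to[[e]], nm)
    nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
  }
  cb <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    paths <- oracle_all_shortest_paths(nbr, s, t)
    if (length(paths) == 0L) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      cb[interior] <- cb[interior] + 1 / length(paths)
    }
  }
  names(cb) <- nm
  cb
}

# Enumerate all set partitions of 1..n via restricted growth strings.
oracle_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) { out[[length(out) + 1L]] <<- rgs; return(invisible()) }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
    rgs[i] <<- 0L
  }
  recurse(1L, 0L)
  out
}

# Maximum-modularity partition by exhaustive search (n <= 8).
oracle_best_modularity <- function(net) {
  nm <- names(net$nodes)
  best <- -Inf; best_part <- NULL
  for (p in oracle_partitions(length(nm))) {
    names(p) <- nm
    q <- modularity_q(net, p)
    if (q > best + 1e-12) { best <- q; best_part <- p }
  }
  list(Q = best, assignment = best_part)
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Random connected simple graph with n_max nodes or fewer; unit weights.
random_connected_graph <- function(n_range = 3:7, p = 0.5) {
  repeat {
    n <- sample(n_range, 1L)
    nodes <- sprintf("v%02d", seq_len(n))
    pairs <- t(combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (sum(keep) == 0L) next
    net <- cooc_from_edges(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
    if (net$N == n && length(litkg:::cooc_components(net)) == 1L) return(net)
  }
}

# Planted-partition (stochastic block model) graph: `blocks` blocks of
# `size` nodes, within-block edge probability p_in, between p_out.
# Returns the graph restricted to its giant component together with the
# planted labels of the retained nodes.
planted_partition_graph <- function(blocks = 4L, size = 20L,
                                    p_in = 0.3, p_out = 0.01) {
  n <- blocks * size
  lab <- rep(seq_len(blocks), each = size)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(n, 2))
  same <- lab[pairs[, 1]] == lab[pairs[, 2]]
  keep <- stats::runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  net <- cooc_from_edges(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
  gc <- suppressMessages(giant_component(net))
  planted <- lab[match(names(gc$nodes), nodes)]
  names(planted) <- names(gc$nodes)
  list(net = gc, planted = planted)
}
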
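# Walktrap community detection, implemented from scratch.
#
# Short random walks on a weighted graph tend to stay inside dense
# subgraphs, so the t-step visit distribution of a node characterizes its
# community. Walktrap defines the squared distance between communities
#
#   r2(C1, C2) = sum_k (Phat_C1k - Phat_C2k)^2 / d(k)
#
# where Phat_C is the community-averaged t-step distribution and d(k) the
# weighted degree of k, and greedily merges the ADJACENT pair of
# communities minimizing the mean squared-distance increase
#
#   dsigma = (1/N) * |C1||C2| / (|C1| + |C2|) * r2(C1, C2).
#
# After N-1 merges the dendrogram is cut at the level maximizing the
# weighted modularity Q = sum_c (w_c/m - (d_c/2m)^2).
#
# Following the reference implementation, the walk itself runs on the
# graph with a unit self-loop per node (aperiodic lazy walk); modularity
# is computed on the graph as given.

#' t-step random-walk transition probabilities
#'
#' Builds the row-stochastic transition matrix `P = D^-1 W` from the
#' weighted adjacency and returns its t-th power. With `lazy = TRUE` a
#' unit self-loop is added to every node before normalization -- the
#' convention of the reference Walktrap implementation, which keeps the
#' walk aperiodic (a plain walk on a bipartite-ish graph oscillates and
#' its t-step distribution carries a parity artifact). Rows of the result
#' sum to 1 either way.
#'
#' @param net a connected `cooc_network` with at least 2 nodes.
#' @param t walk length, a positive integer.
#' @param lazy add unit self-loops (reference Walktrap behavior)?
#' @return an N x N matrix of t-step visit probabilities.
#' @export
transition_powers <- function(net, t = 4L, lazy = FALSE) {
  stopifnot(t >= 1L)
  if (net$N < 2L) stop("need at least 2 nodes")
  W <- adjacency_matrix(net)
  if (any(rowSums(W) == 0))
    stop("isolated node(s) present; prune with giant_component() first")
  if (lazy) W <- W + diag(net$N)
  P <- W / rowSums(W)
  Pt <- P
  if (t > 1L) for (i in seq.int(2L, t)) Pt <- Pt %*% P
  Pt
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c (w_c / m - (d_c / 2m)^2)` with `w_c` the total weight of
#' edges internal to community `c`, `d_c` its total weighted degree, and
#' `m` the total edge weight. The all-in-one partition scores exactly 0.
#'
#' @param net a `cooc_network`.
#' @param assignment named integer vector (node -> community id), total
#'   over the network's nodes.
#' @return modularity Q.
#' @export
modularity_q <- function(net, assignment) {
  m <- sum(net$edges$weight)
  if (m == 0) stop("modularity undefined for a graph with no edge weight")
  nm <- names(net$nodes)
  if (!all(nm %in% names(assignment)))
    stop("assignment must cover every node")
  comm <- assignment[nm]
  W <- net$edges$weight
  same <- comm[net$edges$from] == comm[net$edges$to]
  wd <- tapply(c(W, W), c(net$edges$from, net$edges$to), sum)
  d_c <- tapply(as.numeric(wd[nm]), comm, sum, default = 0)
  d_c[is.na(d_c)] <- 0
  w_c <- tapply(W[same], comm[net$edges$from][same], sum)
  w_all <- structure(numeric(length(d_c)), names = names(d_c))
  if (length(w_c) > 0) w_all[names(w_c)] <- w_c
  sum(w_all / m - (d_c / (2 * m))^2)
}

#' Walktrap community detection
#'
#' Runs the full agglomeration described above: singleton communities,
#' N - 1 merges of adjacent community pairs by minimal `dsigma` (ties
#' broken by the pair with the smallest lower community id, then the
#' smallest higher id), exact size-weighted averaging of community
#' distributions, and a modularity-maximizing cut of the dendrogram.
#' Fully deterministic.
#'
#' @param net a connected weighted `cooc_network`, N >= 2.
#' @param t walk length (default 4, the classic choice).
#' @return a `community_partition`: list with
#'   `assignment` (named integer, node -> 0-based contiguous community id),
#'   `n_communities`, `modularity`, `merge_history`
#'   (data.frame(a, b, dsigma): community ids merged at each step; ids
#'   1..N are singletons in node order, N+k is the community created at
#'   step k), and `t`.
#' @export
walktrap_communities <- function(net, t = 4L) {
  if (net$N < 2L) stop("need at least 2 nodes")
  if (length(cooc_components(net)) > 1L)
    stop("network is disconnected; run giant_component() first")
  n <- net$N
  nm <- names(net$nodes)
  Pt <- transition_powers(net, t, lazy = TRUE)
  W <- adjacency_matrix(net)
  degw <- rowSums(W) + 1   # lazy-walk degrees (unit self-loops), used in r2
  deg_mod <- rowSums(W)    # modularity uses the graph without self-loops
  m_tot <- sum(W) / 2

  n_slots <- 2L * n - 1L
  Phat <- matrix(NA_real_, n_slots, n)   # community-averaged distributions
  Phat[seq_len(n), ] <- Pt
  size <- integer(n_slots); size[seq_len(n)] <- 1L
  d_c <- numeric(n_slots); d_c[seq_len(n)] <- deg_mod   # community degree
  w_int <- numeric(n_slots)                              # internal weight
  active <- logical(n_slots); active[seq_len(n)] <- TRUE
  members <- vector("list", n_slots)
  members[seq_len(n)] <- as.list(seq_len(n))

  CW <- matrix(0, n_slots, n_slots)      # cross weight between communities
  fi <- match(net$edges$from, nm); ti <- match(net$edges$to, nm)
  for (e in seq_along(fi)) {
    CW[fi[[e]], ti[[e]]] <- CW[fi[[e]], ti[[e]]] + net$edges$weight[[e]]
    CW[ti[[e]], fi[[e]]] <- CW[ti[[e]], fi[[e]]] + net$edges$weight[[e]]
  }

  r2 <- function(i, j) sum((Phat[i, ] - Phat[j, ])^2 / degw)
  dsig <- function(i, j)
    (size[i] * size[j]) / (size[i] + size[j]) / n * r2(i, j)

  # dsigma matrix over adjacent active pairs (Inf elsewhere)
  DS <- matrix(Inf, n_slots, n_slots)
  for (e in seq_along(fi)) {
    i <- fi[[e]]; j <- ti[[e]]
    DS[i, j] <- DS[j, i] <- dsig(i, j)
  }

  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       dsigma = numeric(n - 1L))
  # track modularity per level incrementally
  Q_level <- numeric(n)                  # Q after k merges, k = 0..n-1
  Q_level[1] <- sum(-(deg_mod / (2 * m_tot))^2)
  level_members <- vector("list", n)     # community slots active per level

  for (step in seq_len(n - 1L)) {
    # find minimal dsigma among active adjacent pairs; tie-break on
    # (smaller id, larger id)
    sub <- which(active)
    D <- DS[sub, sub, drop = FALSE]
    mn <- min(D)
    hits <- which(D == mn, arr.ind = TRUE)
    lo <- pmin(sub[hits[, 1]], sub[hits[, 2]])
    hi <- pmax(sub[hits[, 1]], sub[hits[, 2]])
    pick <- order(lo, hi)[[1]]
    a <- lo[[pick]]; b <- hi[[pick]]

    new <- n + step
    merges$a[step] <- a; merges$b[step] <- b; merges$dsigma[step] <- mn
    # exact size-weighted average of the t-step distributions
    Phat[new, ] <- (size[a] * Phat[a, ] + size[b] * Phat[b, ]) /
      (size[a] + size[b])
    size[new] <- size[a] + size[b]
    d_c[new] <- d_c[a] + d_c[b]
    w_int[new] <- w_int[a] + w_int[b] + CW[a, b]
    members[[new]] <- c(members[[a]], members[[b]])
    active[c(a, b)] <- FALSE; active[new] <- TRUE

    # modularity change of this merge
    Q_level[step + 1L] <- Q_level[step] + CW[a, b] / m_tot -
      2 * (d_c[a] / (2 * m_tot)) * (d_c[b] / (2 * m_tot))

    # merge cross weights and refresh dsigma against neighbors
    CW[new, ] <- CW[a, ] + CW[b, ]
    CW[, new] <- CW[new, ]
    CW[new, new] <- 0
    nbrs <- which(active & CW[new, ] > 0)
    nbrs <- setdiff(nbrs, new)
    if (length(nbrs) > 0L) {
      diffs <- sweep(Phat[nbrs, , drop = FALSE], 2L, Phat[new, ])
      r2v <- as.numeric((diffs^2) %*% (1 / degw))
      dsv <- (size[new] * size[nbrs]) / (size[new] + size[nbrs]) / n * r2v
      DS[new, nbrs] <- dsv
      DS[nbrs, new] <- dsv
    }
    DS[c(a, b), ] <- Inf; DS[, c(a, b)] <- Inf
  }

  best_level <- which.max(Q_level) - 1L  # number of merges performed
  # replay merges to recover the communities at the best level
  alive <- as.list(seq_len(n))
  names(alive) <- as.character(seq_len(n))
  if (best_level > 0L) {
    for (k in seq_len(best_level)) {
      a <- as.character(merges$a[k]); b <- as.character(merges$b[k])
      alive[[as.character(n + k)]] <- c(alive[[a]], alive[[b]])
      alive[[a]] <- NULL; alive[[b]] <- NULL
    }
  }
  # contiguous 0-based ids, ordered by smallest member node index
  comms <- alive[order(vapply(alive, min, 0L))]
  assignment <- integer(n)
  for (k in seq_along(comms)) assignment[comms[[k]]] <- k - 1L
  names(assignment) <- nm

  structure(list(assignment = assignment,
                 n_communities = length(comms),
                 modularity = Q_level[best_level + 1L],
                 merge_history = merges,
                 t = t),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_communities, "communities, Q =",
      format(x$modularity, digits = 6), "(walk length t =", x$t, ")\n")
  invisible(x)
}

#' Write a partition and its dendrogram merge list as CSV
#'
#' @param partition a `community_partition`.
#' @param path output CSV (`node,community`).
#' @param merges_path optional output CSV for the merge list
#'   (`step,a,b,dsigma`).
#' @export
write_partition_csv <- function(partition, path, merges_path = NULL) {
  df <- data.frame(node = names(partition$assignment),
                   community = unname(partition$assignment),
                   stringsAsFactors = FALSE)
  write_csv_stable(df, path)
  if (!is.null(merges_path)) {
    mh <- partition$merge_history
    mh <- data.frame(step = seq_len(nrow(mh)), a = mh$a, b = mh$b,
                     dsigma = mh$dsigma)
    write_csv_stable(mh, merges_path)
  }
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  df <- read_csv_stable(path)
  assignment <- as.integer(df$community)
  names(assignment) <- df$node
  assignment
}
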
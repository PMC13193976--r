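# Embedding-based keyword standardization.
#
# Raw keyword variants ("Bone Loss", "bone loss", "Osteopenia") are mapped to
# canonical keywords by (1) embedding each normalized term as a unit vector,
# (2) joining term pairs whose cosine similarity reaches a threshold tau
# (default 0.85), (3) taking connected components of that threshold graph as
# synonym clusters, and (4) electing the most frequent member of each cluster
# as its canonical keyword.

#' Normalize a raw keyword for embedding lookup
#'
#' Case-folds, collapses internal whitespace, and strips trailing
#' punctuation, so trivially different spellings collapse before any
#' similarity computation.
#'
#' @param x character vector of raw keywords.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  sub("[[:punct:]]+$", "", x)
}

#' Embedding providers
#'
#' An embedding provider is a function `function(terms)` returning a numeric
#' matrix with one row per term (rownames = terms). Three providers are
#' bundled:
#'
#' * `file_provider(path)` reads a term-to-vector table from a JSON Lines
#'   file of `{"term": ..., "vector": [...]}` objects.
#' * `hash_provider(dim)` is a deterministic stand-in for plumbing tests:
#'   each term is hashed to an RNG seed and embedded as a normalized
#'   Gaussian vector, so distinct terms are near-orthogonal.
#' * `vocabulary_provider(embeddings)` wraps the matrix produced by
#'   [gen_embeddings()] for the synthetic vocabulary.
#'
#' Users wiring a hosted embedding API implement the same contract; the
#' library itself never performs network calls.
#'
#' @param path path to a JSON Lines embedding table.
#' @param dim embedding dimension for the hash provider.
#' @param embeddings a term-by-dimension matrix with rownames.
#' @return a provider function.
#' @name providers
NULL

#' @rdname providers
#' @export
file_provider <- function(path) {
  objs <- read_jsonl(path)
  terms <- vapply(objs, function(o) as.character(o$term), "")
  mat <- do.call(rbind, lapply(objs, function(o) as.numeric(o$vector)))
  rownames(mat) <- normalize_term(terms)
  function(terms) {
    terms <- normalize_term(terms)
    miss <- setdiff(terms, rownames(mat))
    if (length(miss) > 0L)
      stop("embedding provider has no vector for: ",
           paste(sort_c(miss), collapse = ", "))
    mat[terms, , drop = FALSE]
  }
}

#' @rdname providers
#' @export
hash_provider <- function(dim = 64L) {
  force(dim)
  function(terms) {
    terms <- normalize_term(terms)
    mat <- t(vapply(terms, function(tm) {
      with_seed(fnv1a(tm), stats::rnorm(dim))
    }, numeric(dim)))
    rownames(mat) <- terms
    mat
  }
}

#' @rdname providers
#' @export
vocabulary_provider <- function(embeddings) {
  mat <- embeddings
  rownames(mat) <- normalize_term(rownames(mat))
  function(terms) {
    terms <- normalize_term(terms)
    miss <- setdiff(terms, rownames(mat))
    if (length(miss) > 0L)
      stop("embedding provider has no vector for: ",
           paste(sort_c(miss), collapse = ", "))
    mat[terms, , drop = FALSE]
  }
}

#' Write an embedding table usable by `file_provider`
#'
#' @param embeddings term-by-dimension matrix with rownames.
#' @param path output path.
#' @export
write_embeddings_jsonl <- function(embeddings, path) {
  objs <- lapply(rownames(embeddings), function(tm) {
    list(term = tm, vector = as.numeric(embeddings[tm, ]))
  })
  write_jsonl(objs, path)
}

#' Embed a set of terms as unit vectors
#'
#' Terms are normalized ([normalize_term()]), duplicates collapse to a
#' single embedding, and the provider's vectors are re-normalized to unit L2
#' norm. A provider that cannot supply a term raises an error listing the
#' missing terms; there are no silent zero vectors.
#'
#' @param terms character vector of raw terms.
#' @param provider an embedding provider (see [providers]).
#' @return a matrix, one row per unique normalized term, unit L2 rows.
#' @export
embed_terms <- function(terms, provider) {
  terms <- unique(normalize_term(terms))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  mat <- provider(terms)
  stopifnot(is.matrix(mat), nrow(mat) == length(terms))
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) stop("provider returned a zero vector")
  mat <- mat / norms
  rownames(mat) <- terms
  mat
}

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (|u| |v|)`; symmetric, in `[-1, 1]`.
#'
#' @param u,v numeric vectors of equal length and nonzero norm.
#' @return a scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Cluster terms by a cosine-similarity threshold
#'
#' Builds a graph joining every term pair whose cosine similarity is at
#' least `tau` and returns its connected components as synonym clusters
#' (single-linkage reading of "pairs above threshold were grouped"). With
#' `linkage = "complete"` a cluster must instead be a clique of
#' above-threshold pairs (greedy merge of components refined to cliques is
#' not attempted; complete linkage runs agglomeratively on similarity).
#'
#' Every term belongs to exactly one cluster; singletons are allowed.
#' Raising `tau` only refines the partition (it never merges clusters).
#'
#' @param embeddings unit-row matrix from [embed_terms()].
#' @param tau threshold in (0, 1].
#' @param linkage `"single"` (connected components, default) or
#'   `"complete"`.
#' @return list of character vectors (cluster members), ordered by first
#'   member appearance.
#' @export
cluster_by_threshold <- function(embeddings, tau = 0.85,
                                 linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (!(tau > 0 && tau <= 1)) stop("tau must lie in (0, 1]")
  n <- nrow(embeddings)
  if (is.null(n) || n == 0L) return(list())
  terms <- rownames(embeddings)
  if (n == 1L) return(list(terms))
  S <- embeddings %*% t(embeddings)  # unit rows: entries are cosines
  if (linkage == "single") {
    adj <- S >= tau
    diag(adj) <- FALSE
    comp <- components_from_adjacency(adj)
    # component ids are assigned in discovery order, so splitting on them
    # already orders clusters by first member appearance
    unname(lapply(split(seq_len(n), comp), function(ix) terms[ix]))
  } else {
    complete_linkage_clusters(S, terms, tau)
  }
}

# Connected components via BFS on a logical adjacency matrix.
# Returns an integer component id per node (1-based, in discovery order).
components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Agglomerative complete-linkage at threshold tau: repeatedly merge the two
# clusters whose minimum pairwise similarity is maximal, while >= tau.
complete_linkage_clusters <- function(S, terms, tau) {
  clusters <- as.list(seq_along(terms))
  repeat {
    best <- NULL; best_sim <- -Inf
    k <- length(clusters)
    if (k < 2L) break
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      m <- min(S[clusters[[i]], clusters[[j]]])
      if (m >= tau && m > best_sim) { best <- c(i, j); best_sim <- m }
    }
    if (is.null(best)) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lapply(clusters, function(ix) terms[sort(ix)])
}

#' Elect canonical keywords and build a keyword map
#'
#' Within each cluster the member with the highest corpus frequency becomes
#' the canonical keyword (ties broken by shortest term, then
#' lexicographically). The returned map sends every member -- and any
#' raw-case variants supplied via `raw_terms` -- to its canonical term, and
#' is idempotent (canonicals map to themselves).
#'
#' @param clusters list of character vectors from [cluster_by_threshold()].
#' @param frequencies named numeric vector, term -> corpus frequency
#'   (missing terms count 0).
#' @param tau the threshold used (stored on the map).
#' @param raw_terms optional character vector of original-case raw terms to
#'   include as extra keys (mapped through their normalized form).
#' @return a `keyword_map`: list with `mapping` (named character vector) and
#'   `tau`.
#' @export
canonicalize <- function(clusters, frequencies = numeric(0), tau = 0.85,
                         raw_terms = NULL) {
  mapping <- character(0)
  for (cl in clusters) {
    freq <- unname(frequencies[cl])
    freq[is.na(freq)] <- 0
    ord <- order(-freq, nchar(cl), cl, method = "radix")
    canon <- cl[ord[[1]]]
    m <- rep(canon, length(cl))
    names(m) <- cl
    mapping <- c(mapping, m)
  }
  if (!is.null(raw_terms)) {
    raw_terms <- unique(raw_terms)
    norm <- normalize_term(raw_terms)
    extra <- mapping[norm]
    keep <- !is.na(extra) & !(raw_terms %in% names(mapping))
    add <- extra[keep]
    names(add) <- raw_terms[keep]
    mapping <- c(mapping, add)
  }
  structure(list(mapping = mapping, tau = tau), class = "keyword_map")
}

#' Apply a keyword map
#'
#' Unmapped terms map to their normalized selves (with a warning when
#' `warn = TRUE`), keeping the map total over any vocabulary.
#'
#' @param map a `keyword_map`.
#' @param terms character vector of raw terms.
#' @param warn warn on unmapped terms?
#' @return character vector of canonical terms.
#' @export
map_keywords <- function(map, terms, warn = FALSE) {
  norm <- normalize_term(terms)
  out <- map$mapping[terms]          # exact raw-form matches first
  idx <- is.na(out)
  out[idx] <- map$mapping[norm[idx]] # then normalized-form matches
  still <- is.na(out)
  if (any(still)) {
    if (warn)
      warning("unmapped terms map to themselves: ",
              paste(sort_c(unique(terms[still])), collapse = ", "),
              call. = FALSE)
    out[still] <- norm[still]
  }
  unname(out)
}

#' Build a keyword map from a corpus
#'
#' Convenience wrapper: collects all raw keywords, embeds them, clusters at
#' `tau`, and canonicalizes using corpus frequencies (number of records in
#' which each normalized term occurs).
#'
#' @param records a `biblio_corpus`.
#' @param provider an embedding provider.
#' @param tau similarity threshold (default 0.85).
#' @param linkage clustering linkage, see [cluster_by_threshold()].
#' @return a `keyword_map`.
#' @export
standardize_keywords <- function(records, provider, tau = 0.85,
                                 linkage = "single") {
  raw <- unlist(records$keywords, use.names = FALSE)
  if (length(raw) == 0L)
    return(structure(list(mapping = character(0), tau = tau),
                     class = "keyword_map"))
  freq_tab <- table(unlist(lapply(records$keywords, function(k)
    unique(normalize_term(k)))))
  freqs <- as.numeric(freq_tab)
  names(freqs) <- names(freq_tab)
  emb <- embed_terms(raw, provider)
  clusters <- cluster_by_threshold(emb, tau = tau, linkage = linkage)
  canonicalize(clusters, freqs, tau = tau, raw_terms = raw)
}

#' Write / read a keyword map as two-column CSV
#'
#' Columns `raw,canonical`; rows sorted by raw term for byte-stable output.
#'
#' @param map a `keyword_map`.
#' @param path file path.
#' @param tau threshold recorded on a freshly read map.
#' @export
write_keyword_map <- function(map, path) {
  df <- data.frame(raw = names(map$mapping),
                   canonical = unname(map$mapping),
                   stringsAsFactors = FALSE)
  df <- df[order(df$raw, method = "radix"), , drop = FALSE]
  write_csv_stable(df, path)
}

#' @rdname write_keyword_map
#' @export
read_keyword_map <- function(path, tau = 0.85) {
  df <- read_csv_stable(path)
  mapping <- df$canonical
  names(mapping) <- df$raw
  structure(list(mapping = mapping, tau = tau), class = "keyword_map")
}
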
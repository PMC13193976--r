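# Entity-relation knowledge graphs from subject-predicate-object triples,
# with topological classification of hub, bridge, and emerging nodes.
#
# Triples are plain data.frames with columns
#   subject, predicate, object : non-empty strings
#   domain    : tag from a configured set (e.g. inflammation, immunity,
#               gut, biosensing)
#   source_id : provenance record id
# and an optional multiplicity column added when duplicates are merged.

#' Closed verb lexicon of the bundled mock extractor
#' @export
MOCK_VERBS <- c("is associated with", "increases", "decreases", "inhibits",
                "promotes")

#' Deterministic mock triple extractor
#'
#' A stand-in honoring the extractor contract used by [extract_triples()]:
#' it matches `"<A> <verb> <B>"` clauses over the closed verb lexicon
#' [MOCK_VERBS]. Sentences are split on `.;`, clauses on `", "` and
#' `" and "`; a clause with no subject of its own (e.g. the second conjunct
#' of "X promotes A and inhibits B") inherits the previous clause's
#' subject. Returns a list of `list(subject=, predicate=, object=)`.
#'
#' @param text a sentence or abstract.
#' @return list of triple-shaped lists.
#' @export
mock_extractor <- function(text) {
  out <- list()
  sentences <- unlist(strsplit(text, "[.;]\\s*"))
  for (s in sentences) {
    clauses <- unlist(strsplit(s, ",\\s+|\\s+and\\s+"))
    subject <- NULL
    for (cl in clauses) {
      cl <- trimws(cl)
      if (!nzchar(cl)) next
      hit <- NULL
      for (verb in MOCK_VERBS) {
        pat <- paste0("\\b", gsub(" ", "\\\\s+", verb), "\\b")
        m <- regexpr(pat, cl, ignore.case = TRUE)
        if (m > 0) { hit <- verb; pos <- m; len <- attr(m, "match.length"); break }
      }
      if (is.null(hit)) next
      subj <- trimws(substr(cl, 1L, pos - 1L))
      obj <- trimws(substr(cl, pos + len, nchar(cl)))
      if (!nzchar(subj) && !is.null(subject)) subj <- subject
      out[[length(out) + 1L]] <- list(subject = subj, predicate = tolower(hit),
                                      object = obj)
      if (nzchar(subj)) subject <- subj
    }
  }
  out
}

#' Extract validated triples from a text
#'
#' Runs an extractor (any function returning a list of objects with
#' `subject`, `predicate`, `object` fields -- the bundled [mock_extractor()]
#' by default), validates each item (all three fields present and
#' non-empty after trimming), drops malformed items into a noise tally
#' (mirroring the manual filtering of extractor noise), and de-duplicates
#' within the text.
#'
#' @param text input sentence or abstract.
#' @param extractor extractor function.
#' @param domain domain tag attached to every extracted triple.
#' @param source_id provenance id attached to every triple.
#' @return a triple data.frame with attribute `noise_tally` = number of
#'   malformed extractor items dropped.
#' @export
extract_triples <- function(text, extractor = mock_extractor,
                            domain = "unspecified", source_id = "") {
  items <- extractor(text)
  noise <- 0L
  keep <- list()
  seen <- character(0)
  for (it in items) {
    s <- trimws(it$subject %||% "")
    p <- trimws(it$predicate %||% "")
    o <- trimws(it$object %||% "")
    if (!nzchar(s) || !nzchar(p) || !nzchar(o)) { noise <- noise + 1L; next }
    key <- paste(s, p, o, sep = "\u0001")
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1L]] <- list(subject = s, predicate = p, object = o)
  }
  df <- data.frame(
    subject = vapply(keep, `[[`, "", "subject"),
    predicate = vapply(keep, `[[`, "", "predicate"),
    object = vapply(keep, `[[`, "", "object"),
    domain = rep(domain, length(keep)),
    source_id = rep(source_id, length(keep)),
    stringsAsFactors = FALSE)
  attr(df, "noise_tally") <- noise
  df
}

#' Normalize triple entities through a keyword map
#'
#' Subject and object strings are passed through the keyword map (terms
#' the map does not know are case-folded as-is), then exact duplicate
#' triples -- same subject, predicate, object, and domain -- are merged
#' into one row with a `multiplicity` count.
#'
#' @param triples a triple data.frame.
#' @param map a `keyword_map`, or `NULL` for case-folding only.
#' @return the normalized, merged triple data.frame.
#' @export
normalize_entities <- function(triples, map = NULL) {
  if (nrow(triples) == 0L) { triples$multiplicity <- integer(0); return(triples) }
  norm <- function(x) if (is.null(map)) normalize_term(x) else
    map_keywords(map, x)
  triples$subject <- norm(triples$subject)
  triples$object <- norm(triples$object)
  mult <- triples$multiplicity %||% rep(1L, nrow(triples))
  key <- paste(triples$subject, triples$predicate, triples$object,
               triples$domain, sep = "\u0001")
  first <- !duplicated(key)
  agg <- tapply(mult, key, sum)
  out <- triples[first, c("subject", "predicate", "object", "domain",
                          "source_id"), drop = FALSE]
  out$multiplicity <- as.integer(agg[key[first]])
  rownames(out) <- NULL
  out
}

#' Assemble a knowledge graph from triples
#'
#' One node per distinct entity; one undirected edge per distinct
#' (subject, object) pair carrying the multiset of predicates and the
#' total multiplicity. A node's domain tags are the union of the domains
#' of its incident triples. Self-relations (subject == object) are dropped
#' with a warning. Topology downstream is undirected: bridging and
#' centrality are symmetric notions even though predicates are directed.
#'
#' @param triples a triple data.frame.
#' @return a `knowledge_graph`: list with `nodes`
#'   (data.frame(entity) + `domains` list-column), `edges`
#'   (data.frame(a, b, multiplicity) + `predicates` list-column), and
#'   `triples` (the retained rows).
#' @export
assemble_kg <- function(triples) {
  if (nrow(triples) == 0L) {
    nodes <- data.frame(entity = character(0), stringsAsFactors = FALSE)
    nodes$domains <- list()
    edges <- data.frame(a = character(0), b = character(0),
                        multiplicity = integer(0), stringsAsFactors = FALSE)
    edges$predicates <- list()
    return(structure(list(nodes = nodes, edges = edges, triples = triples),
                     class = "knowledge_graph"))
  }
  self <- triples$subject == triples$object
  if (any(self)) {
    warning("dropping ", sum(self), " self-relation triple(s)", call. = FALSE)
    triples <- triples[!self, , drop = FALSE]
  }
  mult <- triples$multiplicity %||% rep(1L, nrow(triples))
  ents <- sort_c(unique(c(triples$subject, triples$object)))
  dom_of <- lapply(ents, function(e) {
    sort_c(unique(triples$domain[triples$subject == e | triples$object == e]))
  })
  nodes <- data.frame(entity = ents, stringsAsFactors = FALSE)
  nodes$domains <- dom_of
  swap <- cmp_gt(triples$subject, triples$object)
  lo <- ifelse(swap, triples$object, triples$subject)
  hi <- ifelse(swap, triples$subject, triples$object)
  key <- paste(lo, hi, sep = "\u0001")
  first <- !duplicated(key)
  edges <- data.frame(a = lo[first], b = hi[first],
                      multiplicity = as.integer(tapply(mult, key, sum)[key[first]]),
                      stringsAsFactors = FALSE)
  edges$predicates <- lapply(key[first], function(k)
    sort_c(triples$predicate[key == k]))
  ord <- order(edges$a, edges$b, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, triples = triples),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("knowledge_graph:", nrow(x$nodes), "entities,", nrow(x$edges),
      "edges,", length(unique(unlist(x$nodes$domains))), "domain(s)\n")
  invisible(x)
}

#' View a knowledge graph as a co-occurrence network container
#'
#' Edge weight = triple multiplicity; node count = incident multiplicity
#' sum. Lets the exact centrality machinery ([node_centralities()],
#' [giant_component()]) run unchanged on entity graphs.
#'
#' @param kg a `knowledge_graph`.
#' @return a `cooc_network`.
#' @export
kg_as_network <- function(kg) {
  if (nrow(kg$edges) == 0L)
    return(new_cooc_network(structure(integer(0), names = character(0)),
                            data.frame(from = character(0), to = character(0),
                                       weight = numeric(0))))
  cooc_from_edges(kg$edges$a, kg$edges$b, kg$edges$multiplicity)
}

#' Classify hub, bridge, and emerging nodes
#'
#' Three independent flags per entity:
#' * `is_hub`: among the top `hub_k` nodes by degree centrality (all nodes
#'   tied with the k-th are included);
#' * `is_bridge`: carries two or more distinct domain tags (its relations
#'   span domains);
#' * `is_emerging`: degree centrality strictly below the median AND
#'   betweenness centrality within the top `emerging_q` quantile --
#'   not yet a hotspot, but a structural gatekeeper.
#'
#' Emerging and hub can never coincide (hubs sit at or above the median
#' degree by construction of the strict inequality).
#'
#' @param kg a `knowledge_graph`.
#' @param topology output of [node_centralities()] on `kg_as_network(kg)`
#'   (computed here if omitted), on the giant component.
#' @param hub_k hub count (default 10).
#' @param emerging_q top betweenness quantile for emerging nodes
#'   (default 0.25).
#' @param weighted passed to [node_centralities()] when topology is
#'   computed here.
#' @return data.frame(entity, degree_c, betweenness_c, n_domains, domains,
#'   is_hub, is_bridge, is_emerging).
#' @export
classify_nodes <- function(kg, topology = NULL, hub_k = 10L,
                           emerging_q = 0.25, weighted = FALSE) {
  net <- kg_as_network(kg)
  if (net$N < 3L)
    stop("node classification needs at least 3 connected entities")
  if (is.null(topology)) {
    net <- giant_component(net)
    topology <- node_centralities(net, weighted = weighted,
                                  metrics = c("degree", "betweenness"))
  }
  top <- topology
  dom <- kg$nodes$domains[match(top$node, kg$nodes$entity)]
  n_dom <- lengths(dom)
  med_deg <- stats::median(top$degree_c)
  bw_cut <- stats::quantile(top$betweenness_c, probs = 1 - emerging_q,
                            names = FALSE, type = 7)
  ord <- order(-top$degree_c, top$node, method = "radix")
  is_hub <- logical(nrow(top))
  if (nrow(top) > 0L && hub_k > 0L) {
    kth <- top$degree_c[ord[min(hub_k, nrow(top))]]
    is_hub <- top$degree_c >= kth
  }
  out <- data.frame(entity = top$node,
                    degree_c = top$degree_c,
                    betweenness_c = top$betweenness_c,
                    n_domains = n_dom,
                    domains = vapply(dom, paste, "", collapse = ";"),
                    is_hub = is_hub,
                    is_bridge = n_dom >= 2L,
                    # a graph with many zero-betweenness nodes degenerates
                    # the quantile to 0; a gatekeeper must carry some paths
                    is_emerging = top$degree_c < med_deg &
                      top$betweenness_c >= bw_cut & top$betweenness_c > 0,
                    stringsAsFactors = FALSE)
  out[order(out$entity, method = "radix"), , drop = FALSE]
}

#' Stratified sample of triples for human validation
#'
#' Samples `ceiling(fraction * n)` items without replacement from every
#' stratum (so each non-empty stratum is represented by at least one
#' item), deterministically under the seed. Strata default to the domain
#' tag; pass an explicit grouping vector for extraction clusters.
#'
#' @param triples a triple data.frame.
#' @param fraction sampling fraction in (0, 1], default 0.05 (5%).
#' @param seed integer seed.
#' @param strata optional grouping vector aligned with `triples` rows
#'   (default `triples$domain`).
#' @return the sampled rows, in stratum order.
#' @export
stratified_sample <- function(triples, fraction = 0.05, seed = 1L,
                              strata = NULL) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must lie in (0, 1]")
  if (nrow(triples) == 0L) return(triples)
  strata <- strata %||% triples$domain
  idx <- split(seq_len(nrow(triples)), strata)
  picked <- unlist(lapply(sort_c(names(idx)), function(s) {
    ix <- idx[[s]]
    k <- ceiling(fraction * length(ix))
    with_seed(child_seed(seed, paste0("stratum:", s)),
              if (length(ix) == 1L) ix else sort(sample(ix, k)))
  }), use.names = FALSE)
  out <- triples[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two equal-length categorical label
#' vectors: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed
#' agreement rate and `p_e = sum_c marginal_a(c) * marginal_b(c)`. When
#' `p_e = 1` (both raters constant and equal) kappa is defined as 1.
#' Invariant under relabeling of categories.
#'
#' @param labels_a,labels_b categorical vectors of equal nonzero length.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n == 0L) stop("label vectors must be nonzero length")
  a <- as.character(labels_a); b <- as.character(labels_b)
  p_o <- mean(a == b)
  levs <- union(a, b)
  p_e <- sum(vapply(levs, function(l) mean(a == l) * mean(b == l), 0))
  if (1 - p_e < .Machine$double.eps * 4) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Write triples / knowledge-graph artifacts
#'
#' Triples as JSON Lines of
#' `{"subject","predicate","object","domain","source_id"}`; node
#' classification as CSV; the entity graph as GraphML via
#' [write_graphml()] on [kg_as_network()].
#'
#' @param triples a triple data.frame.
#' @param path file path.
#' @export
write_triples_jsonl <- function(triples, path) {
  objs <- lapply(seq_len(nrow(triples)), function(i) {
    o <- list(subject = triples$subject[[i]],
              predicate = triples$predicate[[i]],
              object = triples$object[[i]],
              domain = triples$domain[[i]],
              source_id = triples$source_id[[i]])
    if (!is.null(triples$multiplicity))
      o$multiplicity <- triples$multiplicity[[i]]
    o
  })
  write_jsonl(objs, path)
}

#' @rdname write_triples_jsonl
#' @export
read_triples_jsonl <- function(path) {
  objs <- read_jsonl(path)
  df <- data.frame(
    subject = vapply(objs, function(o) as.character(o$subject), ""),
    predicate = vapply(objs, function(o) as.character(o$predicate), ""),
    object = vapply(objs, function(o) as.character(o$object), ""),
    domain = vapply(objs, function(o) as.character(o$domain %||% "unspecified"), ""),
    source_id = vapply(objs, function(o) as.character(o$source_id %||% ""), ""),
    stringsAsFactors = FALSE)
  mult <- vapply(objs, function(o) as.integer(o$multiplicity %||% 1L), 0L)
  if (any(mult != 1L)) df$multiplicity <- mult
  df
}

#' Write node classification as CSV
#'
#' @param classification output of [classify_nodes()].
#' @param path file path.
#' @export
write_classification_csv <- function(classification, path) {
  write_csv_stable(classification, path)
}
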
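test_that("spec validation refuses inseparable or inverted parameters", {
  expect_error(synthetic_spec(within_sim = 0.6, between_sim = 0.6),
               "inseparable")
  expect_error(synthetic_spec(group_size_range = c(4, 2)), "inverted")
  expect_error(synthetic_spec(n_records = 0), "positive")
  expect_error(synthetic_spec(cross_theme_rate = 1.2), "cross_theme_rate")
  expect_error(synthetic_spec(n_groups = 5, n_themes = 8), "per theme")
})

test_that("vocabulary generation is seeded, counts out, and crowns canonicals", {
  spec <- synthetic_spec(n_groups = 4, group_size_range = c(2, 2),
                         n_themes = 2, n_future_themes = 2, seed = 5)
  v <- gen_vocabulary(spec)
  expect_equal(length(unique(v$group)), 4L)
  expect_equal(nrow(v), 8L)
  expect_identical(v, gen_vocabulary(spec))  # bit-reproducible
  for (s in 1:20) {
    vv <- gen_vocabulary(synthetic_spec(seed = s))
    by_g <- split(vv, vv$group)
    for (g in by_g)
      expect_gt(g$freq[g$is_canonical], max(c(g$freq[!g$is_canonical], 0)))
  }
})

test_that("generated embeddings honor the planted cosine bounds", {
  spec <- synthetic_spec(seed = 8)
  v <- gen_vocabulary(spec)
  e <- gen_embeddings(v, spec)
  expect_equal(unname(sqrt(rowSums(e^2))), rep(1, nrow(e)), tolerance = 1e-9)
  expect_identical(e, gen_embeddings(v, spec))
  gid <- v$group[match(rownames(e), v$term)]
  S <- e %*% t(e)
  same <- outer(gid, gid, `==`); diag(same) <- NA
  expect_gte(min(S[same & !is.na(same)]), spec$within_sim)
  expect_lte(max(S[!same & !is.na(same)]), spec$between_sim)
  expect_error(gen_embeddings(v, synthetic_spec(embed_dim = 4)), "at least 8")
})

test_that("corpus generation plants the future-theme co-occurrence signature", {
  spec <- synthetic_spec(seed = 10)
  v <- gen_vocabulary(spec)
  corpus <- gen_corpus(v, spec)
  expect_equal(nrow(corpus), spec$n_records)
  expect_identical(corpus$keywords, gen_corpus(v, spec)$keywords)
  canon_map <- canonicalize(split(v$term, v$group),
                            structure(v$freq, names = v$term))
  net <- build_cooccurrence(corpus, canon_map)
  canon_of_theme <- function(th) {
    unname(canon_map$mapping[v$term[v$theme == th & v$is_canonical]])
  }
  fut <- unlist(lapply(unique(v$theme[v$future]), canon_of_theme))
  # future keywords never co-occur with each other
  expect_false(any(net$edges$from %in% fut & net$edges$to %in% fut))
  # but each carries substantial external weight
  for (f in fut)
    expect_gt(sum(net$edges$weight[net$edges$from == f | net$edges$to == f]),
              0)
})

test_that("with no cross-theme leakage, themes are edge-disjoint", {
  spec <- synthetic_spec(n_future_themes = 0, cross_theme_rate = 0,
                         n_groups = 12, n_themes = 4, n_records = 150,
                         seed = 3)
  v <- gen_vocabulary(spec)
  corpus <- gen_corpus(v, spec)
  map <- canonicalize(split(v$term, v$group),
                      structure(v$freq, names = v$term))
  net <- build_cooccurrence(corpus, map)
  canon_theme <- v$theme[v$is_canonical]
  names(canon_theme) <- unname(map$mapping[v$term[v$is_canonical]])
  expect_false(any(canon_theme[net$edges$from] != canon_theme[net$edges$to]))
})

test_that("corpus years rise linearly in expectation and citations are geometric-ish", {
  spec <- synthetic_spec(seed = 21)
  corpus <- gen_corpus(gen_vocabulary(spec), spec)
  fit <- annual_trend(corpus)
  expect_gt(fit$slope, 0)
  expect_true(all(corpus$times_cited >= 0L))
  tiny <- synthetic_spec(n_groups = 12, n_themes = 10,
                         group_size_range = c(1, 1),
                         keywords_per_record = c(3, 30), seed = 1)
  expect_error(gen_corpus(gen_vocabulary(tiny), tiny), "smaller")
})

test_that("planted triple topology matches its contract", {
  domains <- c("inflammation", "immunity", "gut")
  tri <- gen_triples(domains, synthetic_spec(seed = 6))
  planted <- attr(tri, "planted")
  expect_identical(tri, gen_triples(domains, synthetic_spec(seed = 6)))
  kg <- assemble_kg(tri)
  net <- kg_as_network(kg)
  deg <- table(c(kg$edges$a, kg$edges$b))
  for (d in domains) {
    dom_nodes <- grep(paste0("^", d, "_"), names(deg), value = TRUE)
    hub <- paste0(d, "_hub")
    expect_equal(names(which.max(deg[dom_nodes])), hub)
    expect_gt(unname(deg[hub]), max(deg[setdiff(dom_nodes, hub)]))
  }
  # bridge entities carry >= 2 domain tags
  for (b in planted$bridges)
    expect_gte(length(kg$nodes$domains[kg$nodes$entity == b][[1]]), 2L)
  # emerging entities: degree below the graph median, top betweenness by
  # exhaustive enumeration
  bw <- oracle_betweenness(net)
  for (e in planted$emerging) {
    expect_lt(unname(deg[e]), median(as.numeric(deg)))
    expect_gte(unname(bw[e]), unname(stats::quantile(bw, 0.75)))
  }
  expect_error(gen_triples("inflammation", synthetic_spec(seed = 1),
                           n_bridges = 1), "at least 2 domains")
})

test_that("annotation pairs hit the closed-form kappa", {
  p <- gen_annotation_pair(500, 1.0, seed = 2)
  expect_identical(p$a, p$b)
  expect_equal(cohens_kappa(p$a, p$b), 1)
  k9 <- cohens_kappa(gen_annotation_pair(10000, 0.9, seed = 3)$a,
                     gen_annotation_pair(10000, 0.9, seed = 3)$b)
  expect_lt(abs(k9 - 0.8), 0.05)
  k5 <- cohens_kappa(gen_annotation_pair(10000, 0.5, seed = 4)$a,
                     gen_annotation_pair(10000, 0.5, seed = 4)$b)
  expect_lt(abs(k5), 0.05)
  expect_error(gen_annotation_pair(10, 0.3), "agreement")
})

test_that("standardization recovers planted groups across seeds", {
  for (s in 1:20) {
    spec <- synthetic_spec(seed = s)
    v <- gen_vocabulary(spec)
    emb <- embed_terms(v$term, vocabulary_provider(gen_embeddings(v, spec)))
    clusters <- cluster_by_threshold(emb, tau = 0.85)
    planted <- lapply(split(v$term, v$group), normalize_term)
    expect_equal(length(clusters), length(planted))
    key <- function(cls) sort(unname(vapply(cls, function(x) paste(sort(x), collapse = "|"), "")))
    expect_identical(key(clusters), key(planted))
    # canonical election by planted frequency
    freqs <- structure(v$freq, names = normalize_term(v$term))
    map <- canonicalize(clusters, freqs)
    planted_canon <- normalize_term(v$term[v$is_canonical])
    expect_setequal(unique(unname(map$mapping)), planted_canon)
  }
})
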
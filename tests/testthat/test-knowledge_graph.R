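test_that("the mock extractor parses verb clauses including shared subjects", {
  t1 <- extract_triples("TNF-alpha increases bone resorption.")
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$subject, "TNF-alpha")
  expect_equal(t1$predicate, "increases")
  expect_equal(t1$object, "bone resorption")
  t2 <- extract_triples("IL-6 promotes osteoclastogenesis and inhibits OPG.")
  expect_equal(nrow(t2), 2L)
  expect_equal(t2$subject, c("IL-6", "IL-6"))  # subject inherited
  expect_equal(t2$predicate, c("promotes", "inhibits"))
  t3 <- extract_triples("Spermidine is associated with bone mineral density.")
  expect_equal(t3$predicate, "is associated with")
})

test_that("malformed extractor items land in the noise tally, exactly", {
  noisy_extractor <- function(text) list(
    list(subject = "A", predicate = "increases", object = "B"),
    list(subject = "C", predicate = "inhibits"),            # no object
    list(subject = "", predicate = "promotes", object = "D"),
    list(subject = "A", predicate = "increases", object = "B"))  # duplicate
  out <- extract_triples("ignored", noisy_extractor, domain = "inflammation")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "noise_tally"), 2L)
  expect_equal(attr(out, "noise_tally") / 4, 0.5)  # planted malformed fraction
})

test_that("entity normalization maps through the keyword map and merges duplicates", {
  tri <- data.frame(subject = c("osteoprotegerin", "Osteoprotegerin", "IL-6"),
                    predicate = c("inhibits", "inhibits", "promotes"),
                    object = c("RANKL", "rankl", "bone loss"),
                    domain = "inflammation", source_id = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  map <- canonicalize(list(c("osteoprotegerin", "opg")),
                      c(opg = 10, osteoprotegerin = 4))
  out <- normalize_entities(tri, map)
  expect_equal(nrow(out), 2L)
  row <- out[out$object == "rankl", ]
  expect_equal(row$subject, "opg")
  expect_equal(row$multiplicity, 2L)  # case-folded duplicates merged
})

test_that("knowledge-graph assembly symmetrizes edges and drops self-relations", {
  tri <- data.frame(subject = c("A", "B", "C", "C"),
                    predicate = c("increases", "decreases", "promotes",
                                  "inhibits"),
                    object = c("B", "A", "D", "C"),
                    domain = c("inflammation", "immunity", "gut", "gut"),
                    source_id = "s", stringsAsFactors = FALSE)
  expect_warning(kg <- assemble_kg(tri), "self-relation")
  expect_equal(nrow(kg$nodes), 4L)
  expect_equal(nrow(kg$edges), 2L)
  ab <- kg$edges[kg$edges$a == "A", ]
  expect_equal(ab$multiplicity, 2L)
  expect_setequal(ab$predicates[[1]], c("increases", "decreases"))
  # node domain tags are unions over incident triples
  expect_setequal(kg$nodes$domains[kg$nodes$entity == "A"][[1]],
                  c("inflammation", "immunity"))
  empty <- assemble_kg(tri[0, ])
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("the barbell worked example flags the connector as emerging", {
  # two K4s joined through a degree-2 node b: below-median degree,
  # maximal betweenness
  left <- t(combn(c("l1", "l2", "l3", "l4"), 2))
  right <- t(combn(c("r1", "r2", "r3", "r4"), 2))
  tri <- data.frame(
    subject = c(left[, 1], right[, 1], "l1", "b"),
    predicate = "is associated with",
    object = c(left[, 2], right[, 2], "b", "r1"),
    domain = c(rep("inflammation", 6), rep("immunity", 6),
               "inflammation", "immunity"),
    source_id = "s", stringsAsFactors = FALSE)
  kg <- assemble_kg(tri)
  cls <- classify_nodes(kg, hub_k = 3, emerging_q = 0.25)
  b <- cls[cls$entity == "b", ]
  expect_true(b$is_emerging)
  expect_true(b$is_bridge)      # tagged in both domains
  expect_false(b$is_hub)
  expect_equal(max(cls$betweenness_c), b$betweenness_c)
  expect_false(any(cls$is_emerging & cls$is_hub))
})

test_that("emerging set is empty on vertex-transitive graphs", {
  ring <- sprintf("n%d", 1:6)
  tri <- data.frame(subject = ring, predicate = "increases",
                    object = ring[c(2:6, 1)], domain = "gut",
                    source_id = "s", stringsAsFactors = FALSE)
  cls <- classify_nodes(assemble_kg(tri))
  expect_false(any(cls$is_emerging))  # nobody is strictly below the median
  k4 <- t(combn(sprintf("k%d", 1:4), 2))
  tri4 <- data.frame(subject = k4[, 1], predicate = "promotes",
                     object = k4[, 2], domain = "gut", source_id = "s",
                     stringsAsFactors = FALSE)
  expect_false(any(classify_nodes(assemble_kg(tri4))$is_emerging))
})

test_that("bridge flag is monotone in added domains", {
  tri <- data.frame(subject = c("A", "B"), predicate = "increases",
                    object = c("B", "C"), domain = "inflammation",
                    source_id = "s", stringsAsFactors = FALSE)
  cls1 <- classify_nodes(assemble_kg(tri))
  expect_false(any(cls1$is_bridge))
  tri2 <- rbind(tri, data.frame(subject = "A", predicate = "inhibits",
                                object = "D", domain = "immunity",
                                source_id = "s"))
  cls2 <- classify_nodes(assemble_kg(tri2))
  expect_true(cls2$is_bridge[cls2$entity == "A"])
})

test_that("planted hubs, bridges, and emerging entities are recovered", {
  domains <- c("inflammation", "immunity", "gut", "biosensing")
  for (s in c(1, 2, 3)) {
    tri <- gen_triples(domains, synthetic_spec(seed = s))
    planted <- attr(tri, "planted")
    kg <- assemble_kg(normalize_entities(tri))
    cls <- classify_nodes(kg)
    expect_true(all(normalize_term(planted$hubs) %in%
                      cls$entity[cls$is_hub]))
    expect_true(all(normalize_term(planted$bridges) %in%
                      cls$entity[cls$is_bridge]))
    expect_true(all(normalize_term(planted$emerging) %in%
                      cls$entity[cls$is_emerging]))
    expect_false(any(grepl("_core", cls$entity[cls$is_emerging])))
  }
})

test_that("stratified sampling takes ceil(fraction*n) per stratum, deterministically", {
  tri <- data.frame(subject = sprintf("s%03d", 1:143),
                    predicate = "increases",
                    object = sprintf("o%03d", 1:143),
                    domain = rep(c("big", "mid", "tiny"), c(100, 40, 3)),
                    source_id = "x", stringsAsFactors = FALSE)
  smp <- stratified_sample(tri, fraction = 0.05, seed = 9)
  expect_equal(unname(table(smp$domain)[c("big", "mid", "tiny")]),
               c(5L, 2L, 1L), ignore_attr = TRUE)
  expect_identical(smp, stratified_sample(tri, fraction = 0.05, seed = 9))
  expect_equal(nrow(stratified_sample(tri, fraction = 1)), nrow(tri))
  expect_error(stratified_sample(tri, fraction = 0), "fraction")
})

test_that("Cohen's kappa matches closed forms and is relabel-invariant", {
  expect_equal(cohens_kappa(c("y", "n", "y"), c("y", "n", "y")), 1)
  a <- rep(c("yes", "no", "yes", "no"), c(40, 40, 10, 10))
  b <- rep(c("yes", "no", "no", "yes"), c(40, 40, 10, 10))
  expect_equal(cohens_kappa(a, b), 0.6)   # p_o=0.8, p_e=0.5
  relabel <- c(yes = "1", no = "2")
  expect_equal(cohens_kappa(relabel[a], relabel[b]), 0.6)
  expect_equal(cohens_kappa(rep("k", 5), rep("k", 5)), 1)  # p_e = 1 case
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
})

test_that("triples round trip through JSON Lines", {
  tri <- gen_triples(c("inflammation", "immunity"),
                     synthetic_spec(seed = 4), n_bridges = 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_triples_jsonl(tri, path)
  back <- read_triples_jsonl(path)
  expect_equal(back[, c("subject", "predicate", "object", "domain")],
               tri[, c("subject", "predicate", "object", "domain")])
})
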
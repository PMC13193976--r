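test_that("co-occurrence counts unique canonical pairs per record", {
  recs <- biblio_corpus(record_id = c("r1", "r2", "r3"), year = 2020L,
                        keywords = list(c("a", "b", "c"), c("a", "b"),
                                        c("A", "a ")))
  net <- build_cooccurrence(recs)
  expect_equal(net$N, 3L)
  expect_equal(net$E, 3L)  # triangle from r1
  w <- net$edges$weight
  names(w) <- paste(net$edges$from, net$edges$to)
  expect_equal(unname(w["a b"]), 2L)     # r1 + r2
  expect_equal(unname(w["a c"]), 1L)
  # r3 holds two raw variants of one canonical: node counted, no edges
  expect_equal(unname(net$nodes["a"]), 3L)
})

test_that("giant component keeps the largest component with lexicographic ties", {
  k3 <- function(x) cooc_from_edges(x[c(1, 1, 2)], x[c(2, 3, 3)])
  both <- cooc_from_edges(c("a", "a", "b", "x", "x", "y", "p"),
                          c("b", "c", "c", "y", "z", "z", "q"))
  expect_message(gc <- giant_component(both), "removed 5")
  expect_setequal(names(gc$nodes), c("a", "b", "c"))  # tie -> contains "a"
  connected <- k3(c("m", "n", "o"))
  expect_identical(giant_component(connected)$nodes, connected$nodes)
})

test_that("graph density follows 2E/(N(N-1)) and needs two nodes", {
  k4 <- cooc_from_edges(c("a","a","a","b","b","c"), c("b","c","d","c","d","d"))
  expect_equal(graph_density(k4), 1)
  path3 <- cooc_from_edges(c("a", "b"), c("b", "c"))
  expect_equal(graph_density(path3), 2 * 2 / (3 * 2))
  # weights are ignored: E counts distinct pairs
  heavy <- cooc_from_edges(c("a", "b"), c("b", "c"), weight = c(9, 9))
  expect_equal(graph_density(heavy), graph_density(path3))
  # edgeless pair of nodes
  pair <- litkg:::induced_subgraph_cooc(
    cooc_from_edges("a", "b", nodes = c(a = 1, b = 1, z = 1)), c("b", "z"))
  expect_equal(graph_density(pair), 0)
  single <- litkg:::induced_subgraph_cooc(path3, "a")
  expect_error(graph_density(single), "2 nodes")
  # adding an edge at fixed N strictly increases density
  tri_closed <- cooc_from_edges(c("a", "b", "a"), c("b", "c", "c"))
  expect_gt(graph_density(tri_closed), graph_density(path3))
})

test_that("star and path centralities match closed forms", {
  star <- cooc_from_edges(rep("h", 4), c("l1", "l2", "l3", "l4"))
  cen <- node_centralities(star)
  h <- cen[cen$node == "h", ]
  expect_equal(h$degree_c, 1)
  expect_equal(h$betweenness_c, 1)
  expect_equal(cen$betweenness_c[cen$node == "l1"], 0)
  path <- node_centralities(cooc_from_edges(c("a", "b"), c("b", "c")))
  expect_equal(path$betweenness_c[path$node == "b"], 1)
  expect_equal(path$closeness_c[path$node == "b"], 1)
  expect_equal(path$closeness_c[path$node == "a"], 2 / 3)
})

test_that("Brandes betweenness equals the exhaustive-path oracle on random graphs", {
  set.seed(2024)
  for (i in 1:30) {
    net <- random_connected_graph()
    adj <- litkg:::adjacency_lists(net)
    raw <- litkg:::brandes_betweenness(adj)
    names(raw) <- adj$names
    expect_equal(raw, oracle_betweenness(net), tolerance = 1e-12)
  }
})

test_that("weighted betweenness uses inverse-weight distances", {
  # a-b-c chain with a heavy shortcut a-c: weighted shortest path a..c goes
  # through the strong direct edge, so b carries no weighted betweenness
  net <- cooc_from_edges(c("a", "b", "a"), c("b", "c", "c"),
                         weight = c(1, 1, 10))
  unw <- node_centralities(net, weighted = FALSE)
  wei <- node_centralities(net, weighted = TRUE)
  expect_equal(wei$betweenness_c[wei$node == "b"], 0)
  expect_equal(unw$betweenness_c[unw$node == "b"], 0)  # direct edge exists too
  # now make the direct edge weak: unweighted still direct, weighted detours
  net2 <- cooc_from_edges(c("a", "b", "a"), c("b", "c", "c"),
                          weight = c(10, 10, 1))
  wei2 <- node_centralities(net2, weighted = TRUE)
  expect_equal(wei2$betweenness_c[wei2$node == "b"], 1)
})

test_that("eigenvector centrality is constant on vertex-transitive graphs", {
  cyc <- cooc_from_edges(c("a", "b", "c", "d", "e"),
                         c("b", "c", "d", "e", "a"))
  ev <- node_centralities(cyc)$eigenvector_c
  expect_lt(diff(range(ev)), 1e-8)
  expect_equal(max(ev), 1)
  kp <- t(combn(c("a", "b", "c", "d", "e"), 2))
  k5 <- cooc_from_edges(kp[, 1], kp[, 2])
  expect_lt(diff(range(node_centralities(k5)$eigenvector_c)), 1e-8)
})

test_that("pendant attachment never lowers the attachment point's betweenness", {
  set.seed(7)
  for (i in 1:10) {
    net <- random_connected_graph(n_range = 4:6)
    cen <- node_centralities(net)
    target <- cen$node[[1]]
    raw_before <- cen$betweenness_c * ((net$N - 1) * (net$N - 2) / 2)
    net2 <- cooc_from_edges(c(net$edges$from, target),
                            c(net$edges$to, "zz_pendant"),
                            c(net$edges$weight, 1))
    cen2 <- node_centralities(net2)
    raw_after <- cen2$betweenness_c * ((net2$N - 1) * (net2$N - 2) / 2)
    expect_gte(raw_after[cen2$node == target] + 1e-9,
               raw_before[cen$node == target])
  }
})

test_that("centralities demand a connected graph", {
  disc <- cooc_from_edges(c("a", "x"), c("b", "y"))
  expect_error(node_centralities(disc), "giant_component")
})

test_that("edge-list export round trips and GraphML is well formed", {
  net <- cooc_from_edges(c("a", "a", "b"), c("b", "c", "c"),
                         weight = c(2, 1, 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_edgelist_csv(net, csv)
  back <- read_edgelist_csv(csv)
  expect_equal(back$edges, net$edges)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  doc <- xml2::read_xml(gml)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")), 3L)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 3L)
})
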
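# Scanpath-to-network encoding, adjacency views, averaging, masking, export.

test_that("the worked scanpath builds the expected 5-node network", {
  net <- build_network(c("could", "humans", "live", "mars", "day",
                         "could", "humans"))
  expect_equal(length(net$nodes), 5L)
  expect_equal(sum(net$weights), 6)
  expect_equal(net$weights["could", "humans"], 2)
  expect_equal(net$weights["humans", "live"], 1)
  expect_equal(net$weights["live", "mars"], 1)
  expect_equal(net$weights["mars", "day"], 1)
  expect_equal(net$weights["day", "could"], 1)
})

test_that("self-loops are suppressed and degenerate scanpaths handled", {
  net1 <- build_network("mars")
  expect_equal(length(net1$nodes), 1L)
  expect_equal(sum(net1$weights), 0)

  net2 <- build_network(c("mars", "mars", "day"))
  expect_equal(length(net2$nodes), 2L)
  expect_equal(sum(net2$weights), 1)
  expect_equal(net2$weights["mars", "day"], 1)

  expect_error(build_network(character(0)), "empty")
})

test_that("total weight conserves transitions minus consecutive refixations", {
  set.seed(11)
  for (rep in 1:20) {
    keys <- sample(letters[1:6], sample(2:40, 1), replace = TRUE)
    net <- build_network(keys)
    refix <- sum(keys[-1] == keys[-length(keys)])
    expect_equal(sum(net$weights), (length(keys) - 1) - refix)
  }
})

test_that("sentence linking can be disabled for cross-boundary saccades", {
  stim <- text_stimulus(list(c("a", "b"), c("c", "d")), text_id = "t")
  rec <- data.frame(participant_id = "p", text_id = "t",
                    sentence_index = c(1L, 1L, 2L, 2L),
                    word_index = c(1L, 2L, 1L, 2L), token = NA,
                    onset_ms = 0:3 * 100, duration_ms = rep(100, 4),
                    stringsAsFactors = FALSE)
  sp <- extract_scanpath(rec, stim)
  linked <- build_network(sp, link_sentences = TRUE)
  unlinked <- build_network(sp, link_sentences = FALSE)
  expect_equal(sum(linked$weights), 3)
  expect_equal(sum(unlinked$weights), 2)
  expect_equal(unlinked$weights["b", "c"], 0)
})

test_that("adjacency views symmetrize correctly and round-trip losslessly", {
  net <- net_from_edges(c("a", "b"), c("b", "a"), c(2, 1))
  undir <- as_adjacency(net, directed = FALSE)
  expect_equal(undir["a", "b"], 3)
  expect_equal(undir["b", "a"], 3)
  dir <- as_adjacency(net, directed = TRUE)
  expect_equal(dir["a", "b"], 2)
  expect_equal(dir["b", "a"], 1)

  set.seed(4)
  for (rep in 1:10) {
    n <- random_weighted_net(sample(2:6, 1))
    back <- from_adjacency(as_adjacency(n, directed = TRUE))
    expect_equal(back$weights, n$weights)
    expect_equal(back$nodes, n$nodes)
  }

  edgeless <- scanpath_network(matrix(0, 3, 3,
                                      dimnames = list(letters[1:3], letters[1:3])))
  expect_true(all(as_adjacency(edgeless, directed = FALSE) == 0))
})

test_that("node degree sums incident weights in both directions", {
  tab <- table1_unique_edges()
  expect_equal(node_degree(tab, "mars"), 5)   # human 1 + on 1 + day 3
  expect_equal(node_degree(tab, "question"), 1)
  expect_error(node_degree(tab, "zebra"), "unknown node")

  iso <- scanpath_network(matrix(0, 2, 2, dimnames = list(c("x", "y"),
                                                          c("x", "y"))))
  expect_equal(node_degree(iso, "x"), 0)

  star <- net_from_edges(rep("hub", 4), paste0("leaf", 1:4))
  expect_equal(node_degree(star, "hub"), 4)
  expect_equal(unname(node_strengths(star)[paste0("leaf", 1:4)]), rep(1, 4))
})

test_that("averaging aligns vocabularies, counts absent edges as zero", {
  n1 <- net_from_edges("a", "b", 2)
  same <- average_networks(list(n1, n1))
  expect_equal(same$weights, n1$weights)

  n2 <- scanpath_network(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b"))))
  avg <- average_networks(list(n1, n2))
  expect_equal(avg$weights["a", "b"], 1)

  nets10 <- c(replicate(9, net_from_edges("a", "b", 1), simplify = FALSE),
              list(net_from_edges("a", "b", 4)))
  expect_equal(average_networks(nets10)$weights["a", "b"], 1.3)

  # union alignment and permutation invariance
  nx <- net_from_edges("a", "c", 6)
  u1 <- average_networks(list(n1, nx))
  u2 <- average_networks(list(nx, n1))
  expect_equal(sort(u1$nodes), c("a", "b", "c"))
  expect_equal(u1$weights[u1$nodes, u1$nodes], u2$weights[u1$nodes, u1$nodes])
  expect_equal(u1$weights["a", "c"], 3)

  expect_error(average_networks(list()), "length")
  m1 <- build_network(scanpath(data.frame(node_key = c("a", "b"),
                                          sentence_index = 1L, word_index = 1:2,
                                          duration_ms = 100), "p1", "textA"))
  m2 <- build_network(scanpath(data.frame(node_key = c("a", "b"),
                                          sentence_index = 1L, word_index = 1:2,
                                          duration_ms = 100), "p2", "textB"))
  expect_error(average_networks(list(m1, m2)), "different texts")
})

test_that("masking filters edges first, then nodes, with strict thresholds", {
  # edge of weight exactly 0.3 is removed under the default cut
  n <- net_from_edges(c("a", "a"), c("b", "c"), c(0.3, 2))
  masked <- apply_mask(n, degree_gt = 0, weight_gt = 0.3)
  expect_false("b" %in% masked$nodes)
  expect_equal(masked$weights["a", "c"], 2)

  # hub with degree 6 and edges of weight 0.5 is retained (6 > 5 strictly)
  hub <- net_from_edges(rep("h", 12), paste0("l", 1:12), 0.5)
  kept <- apply_mask(hub, degree_gt = 5, weight_gt = 0.3)
  expect_true("h" %in% kept$nodes)

  # node whose raw degree clears the cut only through sub-threshold edges is
  # dropped once edges are filtered first
  mixed <- net_from_edges(rep("x", 30), paste0("y", 1:30), 0.2)
  expect_warning(out <- apply_mask(mixed, degree_gt = 5, weight_gt = 0.3),
                 "every node")
  expect_equal(length(suppressWarnings(
    apply_mask(mixed, degree_gt = 5, weight_gt = 0.3))$nodes), 0L)
  expect_equal(length(out$nodes) == 0L || all(node_strengths(out) > 5), TRUE)

  expect_error(apply_mask(n, degree_gt = -1), "non-negative")
})

test_that("masking is monotone in both thresholds", {
  set.seed(9)
  for (rep in 1:8) {
    n <- random_weighted_net(7, p_edge = 0.5, max_w = 4)
    base <- suppressWarnings(apply_mask(n, degree_gt = 2, weight_gt = 1))
    tighter_deg <- suppressWarnings(apply_mask(n, degree_gt = 4, weight_gt = 1))
    tighter_w <- suppressWarnings(apply_mask(n, degree_gt = 2, weight_gt = 2))
    expect_true(all(tighter_deg$nodes %in% base$nodes))
    expect_true(all(tighter_w$nodes %in% base$nodes))
    expect_lte(sum(tighter_deg$weights > 0), sum(base$weights > 0))
    expect_lte(sum(tighter_w$weights > 0), sum(base$weights > 0))
  }
})

test_that("GraphML, GEXF and adjacency CSV exports are readable", {
  net <- build_network(c("could", "humans", "live", "mars", "day",
                         "could", "humans"))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::ecount(g), 5)
  expect_equal(sum(igraph::E(g)$weight), 6)

  gexf <- tempfile(fileext = ".gexf")
  write_gexf(net, gexf)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)), 5L)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)), 5L)

  csv <- tempfile(fileext = ".csv")
  write_adjacency_csv(net, csv)
  adj <- as.matrix(utils::read.csv(csv, row.names = 1, check.names = FALSE))
  expect_equal(unname(adj), unname(net$weights))
})
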
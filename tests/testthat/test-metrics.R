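# The five graph metrics against analytic cases and brute-force oracles.

test_that("density matches the printed-formula evaluation", {
  expect_equal(net_density(complete_net(6)), 1)
  expect_equal(net_density(scanpath_network(table1_matrix())), 14 / 56)
  edgeless <- scanpath_network(matrix(0, 5, 5,
                                      dimnames = list(letters[1:5], letters[1:5])))
  expect_equal(net_density(edgeless), 0)
  one <- scanpath_network(matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_error(net_density(one), "undefined")
})

test_that("centralization separates stars, paths and regular graphs", {
  star <- net_from_edges(rep("hub", 4), paste0("leaf", 1:4))
  expect_equal(net_centralization(star), 1)

  path4 <- net_from_edges(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(net_centralization(path4), 1 / 3)  # strengths (1,2,2,1)

  expect_equal(net_centralization(complete_net(5)), 0)

  two <- net_from_edges("a", "b")
  expect_error(net_centralization(two), "undefined")
})

test_that("unit-weight centralization stays in [0,1]; brute force agrees", {
  set.seed(21)
  for (rep in 1:15) {
    a <- symmetric_graph_5(sample(0:1023, 1))
    net <- net_from_symmetric(a)
    C <- net_centralization(net)
    expect_equal(C, bf_centralization(net$weights))
    expect_gte(net_centralization(net, binarize = TRUE), 0)
    expect_lte(net_centralization(net, binarize = TRUE), 1)
  }
  # degree-regular: ring
  ring <- ring_lattice(8, 2)
  expect_equal(net_centralization(ring), 0)
})

test_that("topology classification uses the conventional bands", {
  expect_equal(as.character(classify_topology(c(0.1, 0.45, 1.0))),
               c("linear", "network", "star"))
  # half-open boundaries
  expect_equal(as.character(classify_topology(c(0, 0.2, 0.4, 0.6))),
               c("linear", "hierarchical", "network", "star"))
  expect_warning(out <- classify_topology(1.4), "clamping")
  expect_equal(as.character(out), "star")
})

test_that("transitivity matches analytic values and the triple-sum oracle", {
  k4 <- complete_net(4)  # every reciprocal unit edge present
  expect_equal(as.numeric(net_transitivity(k4)), 1)

  path <- net_from_edges(c("a", "b", "b", "c"), c("b", "a", "c", "b"))
  expect_equal(as.numeric(net_transitivity(path)), 0)

  w3 <- net_from_edges(c("a", "b", "c"), c("b", "c", "a"), c(2, 1, 1))
  expect_equal(as.numeric(net_transitivity(w3)), 3 / 7)
  expect_equal(as.numeric(net_transitivity(w3)), bf_transitivity(w3$weights))

  # no connected triples: flagged zero, not an error
  pair <- net_from_edges("a", "b")
  tv <- net_transitivity(pair)
  expect_equal(as.numeric(tv), 0)
  expect_true(attr(tv, "undefined"))
})

test_that("on binary symmetric graphs transitivity equals the classic
           clustering coefficient (exhaustive over all 5-node graphs)", {
  for (idx in 0:1023) {
    a <- symmetric_graph_5(idx)
    if (sum(a) == 0) next
    net <- net_from_symmetric(a)
    expect_equal(as.numeric(net_transitivity(net)), bf_transitivity_binary(a),
                 tolerance = 1e-9)
  }
})

test_that("weighted transitivity and clustering match brute force on random graphs", {
  set.seed(31)
  for (rep in 1:20) {
    net <- random_weighted_net(sample(3:5, 1))
    expect_equal(as.numeric(net_transitivity(net)), bf_transitivity(net$weights),
                 tolerance = 1e-9)
    expect_equal(net_clustering(net), bf_clustering(net$weights),
                 tolerance = 1e-9)
  }
})

test_that("shortest distances honor direction and inverse-weight lengths", {
  chain <- net_from_edges(c("a", "b"), c("b", "c"))
  d <- shortest_distances(chain)
  expect_equal(d["a", "c"], 2)
  expect_equal(d["c", "a"], Inf)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  # heavy two-hop route beats the direct unit edge: 1/4 + 1/4 < 1
  par <- net_from_edges(c("a", "a", "x"), c("b", "x", "b"), c(1, 4, 4))
  expect_equal(shortest_distances(par)["a", "b"], 0.5)

  single <- scanpath_network(matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_equal(shortest_distances(single)["a", "a"], 0)
})

test_that("shortest distances agree with exhaustive path enumeration", {
  # all undirected binary graphs on 4 nodes
  for (idx in 0:63) {
    bits <- as.integer(intToBits(idx))[1:6]
    a <- matrix(0, 4, 4)
    a[lower.tri(a)] <- bits
    a <- a + t(a)
    net <- net_from_symmetric(a)
    expect_equal(unname(shortest_distances(net)), bf_distances(net$weights))
  }
  # random weighted directed graphs on 5 nodes
  set.seed(41)
  for (rep in 1:40) {
    net <- random_weighted_net(5, p_edge = 0.35)
    expect_equal(unname(shortest_distances(net)), bf_distances(net$weights),
                 tolerance = 1e-9)
  }
})

test_that("global efficiency hits its analytic limits", {
  expect_equal(net_efficiency(complete_net(8)), 1)
  edgeless <- scanpath_network(matrix(0, 8, 8,
                                      dimnames = list(letters[1:8], letters[1:8])))
  expect_equal(net_efficiency(edgeless), 0)
  # undirected 3-node path: (1+1+1+1+0.5+0.5)/6
  p3 <- net_from_edges(c("a", "b", "b", "c"), c("b", "a", "c", "b"))
  expect_equal(net_efficiency(p3), 5 / 6)
})

test_that("unit-weight efficiency lies in [0,1], 1 iff complete", {
  set.seed(51)
  for (rep in 1:12) {
    a <- symmetric_graph_5(sample(0:1023, 1))
    net <- net_from_symmetric(a)
    E <- net_efficiency(net)
    expect_gte(E, 0)
    expect_lte(E, 1)
    expect_equal(E == 1, all(a[row(a) != col(a)] == 1))
  }
})

test_that("clustering coefficient handles leaves and isolates as zeros", {
  tri <- complete_net(3)
  expect_equal(net_clustering(tri), bf_clustering(tri$weights))
  expect_gt(net_clustering(tri), 0)

  star <- net_from_edges(rep("h", 4), paste0("l", 1:4))
  expect_equal(net_clustering(star), 0)

  iso <- scanpath_network(matrix(0, 4, 4,
                                 dimnames = list(letters[1:4], letters[1:4])))
  expect_equal(net_clustering(iso), 0)
})

test_that("characteristic path length: both modes behave as documented", {
  expect_equal(net_path_length(complete_net(4), "mean_distance"), 1)

  chain <- net_from_edges(c("a", "b"), c("b", "c"))
  expect_equal(net_path_length(chain, "mean_distance"), 4 / 3)

  set.seed(61)
  for (rep in 1:8) {
    net <- random_weighted_net(5, p_edge = 0.4)
    if (sum(net$weights) == 0) next
    expect_identical(net_path_length(net, "as_printed"), net_efficiency(net))
  }

  iso <- scanpath_network(matrix(0, 3, 3,
                                 dimnames = list(letters[1:3], letters[1:3])))
  expect_error(net_path_length(iso, "mean_distance"), "no reachable")
})

test_that("random references preserve size and edge count and are seeded", {
  net <- random_weighted_net(8, p_edge = 0.3)
  m <- sum(net$weights > 0)
  ens <- random_reference(net, n_refs = 10, seed = 99)
  for (ref in ens$refs) {
    expect_equal(length(ref$nodes), 8L)
    expect_equal(sum(ref$weights > 0), m)
    expect_equal(sort(ref$weights[ref$weights > 0]),
                 sort(net$weights[net$weights > 0]))
    expect_equal(net_density(ref), net_density(net))  # same total weight, N
  }
  ens2 <- random_reference(net, n_refs = 10, seed = 99)
  expect_identical(lapply(ens$refs, `[[`, "weights"),
                   lapply(ens2$refs, `[[`, "weights"))
  expect_error(random_reference(net, n_refs = 0, seed = 1), "n_refs")
  iso <- scanpath_network(matrix(0, 3, 3,
                                 dimnames = list(letters[1:3], letters[1:3])))
  expect_error(random_reference(iso, seed = 1), "at least one edge")
})

test_that("the complete graph is its own random reference, giving S = 1", {
  k5 <- complete_net(5)
  ens <- random_reference(k5, n_refs = 5, seed = 3)
  expect_equal(ens$C_rand, net_clustering(k5))
  expect_equal(ens$L_rand, net_path_length(k5))
  S <- net_small_worldness(k5, n_refs = 5, seed = 3)
  expect_equal(as.numeric(S), 1)
})

test_that("a rewired ring lattice is small-world; matched random graphs are not", {
  rl <- ring_lattice(60, 6, p_rewire = 0.1, seed = 5)
  S <- net_small_worldness(rl, n_refs = 10, seed = 6)
  expect_gt(as.numeric(S), 1)

  rnd <- random_network(60, sum(rl$weights > 0), seed = 7)
  S0 <- net_small_worldness(rnd, n_refs = 10, seed = 8)
  expect_lt(abs(as.numeric(S0) - 1), 0.3)
})

test_that("all metrics are invariant under node relabeling", {
  set.seed(71)
  for (rep in 1:8) {
    net <- random_weighted_net(6, p_edge = 0.4)
    if (sum(net$weights) == 0) next
    perm <- sample(6)
    w2 <- net$weights[perm, perm]
    net2 <- scanpath_network(w2)
    expect_equal(net_density(net2), net_density(net))
    expect_equal(net_centralization(net2), net_centralization(net))
    expect_equal(as.numeric(net_transitivity(net2)),
                 as.numeric(net_transitivity(net)))
    expect_equal(net_efficiency(net2), net_efficiency(net))
    expect_equal(net_clustering(net2), net_clustering(net))
  }
})

test_that("metric_set bundles values, provenance, and explicit failures", {
  ms <- metric_set(scanpath_network(table1_matrix()), n_refs = 5, seed = 2)
  expect_s3_class(ms, "metric_set")
  expect_equal(ms$density, 0.25)
  expect_equal(ms$n_refs, 5L)
  expect_equal(ms$l_mode, "mean_distance")

  ms2 <- metric_set(scanpath_network(table1_matrix()), n_refs = 5, seed = 2)
  expect_equal(ms$small_worldness, ms2$small_worldness)  # determinism

  # fully masked-out network: everything flagged, nothing silently dropped
  tiny <- net_from_edges("a", "b", 0.1)
  empty <- suppressWarnings(apply_mask(tiny))
  ms3 <- metric_set(empty)
  expect_true(is.na(ms3$density) && is.na(ms3$small_worldness))
  expect_gt(length(ms3$flags), 0)

  df <- as.data.frame(ms)
  expect_equal(df$density, 0.25)
  expect_equal(nrow(df), 1L)
})

test_that("small-worldness estimates stabilize as the ensemble grows", {
  net <- ring_lattice(40, 4, p_rewire = 0.2, seed = 12)
  spread <- function(n_refs, seeds) {
    vals <- vapply(seeds, function(s) {
      as.numeric(net_small_worldness(net, n_refs = n_refs, seed = s))
    }, numeric(1))
    stats::sd(vals)
  }
  sd_small <- spread(3, 1:12)
  sd_large <- spread(24, 1:12)
  expect_lt(sd_large, sd_small)
})
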
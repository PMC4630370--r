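mk_graph <- function(edges) igraph::graph_from_edgelist(edges, directed = FALSE)

test_that("subnetwork extraction keeps the largest connected component", {
  g <- mk_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                      c("x", "y"), c("e", "x")))
  # one component
  sn <- extract_subnetworks(g, list(T1 = c("a", "b", "c")))
  expect_equal(sort(sn[[1]]$nodes), c("a", "b", "c"))
  # two components of size 5 and 2: keep the 5
  sn2 <- extract_subnetworks(g, list(T2 = c("a", "b", "c", "d", "e", "x", "y")))
  expect_equal(sn2[[1]]$size, 7)  # x connects through e: all connected
  sn3 <- extract_subnetworks(g, list(T3 = c("a", "b", "c", "x", "y")))
  expect_equal(sort(sn3[[1]]$nodes), c("a", "b", "c"))
  expect_equal(sn3[[1]]$size, 3)
  # isolated single node is a size-1 subnetwork; empty terms dropped
  sn4 <- extract_subnetworks(g, list(T4 = "y", T5 = "zzz"))
  expect_length(sn4, 1)
  expect_equal(sn4[[1]]$size, 1)
  # all_components scores each component
  sn5 <- extract_subnetworks(g, list(T3 = c("a", "b", "c", "x", "y")),
                             all_components = TRUE)
  expect_length(sn5, 2)
})

test_that("S_net matches hand computations", {
  g <- mk_graph(rbind(c("A", "B"), c("C", "A"), c("C", "Z")))
  sub <- list(term = "T", nodes = c("A", "B"), size = 2)
  # no touching target
  expect_equal(s_net(sub, c(Q = 1), g)$s_net, 0)
  # peripheral target C: deg 2, one edge into {A,B}, affinity 0.5
  sc <- s_net(sub, c(C = 0.5), g)
  expect_equal(sc$s_net, 0.125)
  expect_equal(sc$n_targets, 1L)
  # fully targeted subnetwork at unit affinity scores 1
  g2 <- mk_graph(rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")))
  sub2 <- list(term = "T2", nodes = c("A", "B", "C", "D"), size = 4)
  expect_equal(s_net(sub2, c(A = 1, B = 1, C = 1, D = 1), g2)$s_net, 1)
})

test_that("S_net is monotone in affinities and peripheral edges", {
  g <- mk_graph(rbind(c("A", "B"), c("C", "A"), c("C", "Z"), c("C", "W")))
  sub <- list(term = "T", nodes = c("A", "B"), size = 2)
  s1 <- s_net(sub, c(C = 0.4), g)$s_net
  s2 <- s_net(sub, c(C = 0.8), g)$s_net
  expect_gt(s2, s1)
  # add an edge from C into the subnetwork: score rises
  g_plus <- igraph::add_edges(g, c("C", "B"))
  expect_gt(s_net(sub, c(C = 0.4), g_plus)$s_net, s1)
  # bounded by touching targets / |V_f|
  expect_lte(s_net(sub, c(C = 1, A = 1), g)$s_net, 2 / 2)
})

test_that("S_net equals brute-force recomputation on generated fixtures", {
  for (s in c(1, 4, 9)) {
    fx <- gen_network_fixture(60, 150, 4, 12, 10, seed = s)
    el <- igraph::as_edgelist(fx$graph, names = TRUE)
    subnets <- extract_subnetworks(fx$graph, fx$term2nodes)
    for (sn in subnets) {
      got <- s_net(sn, fx$targets, fx$graph)
      want <- oracle_s_net(sn$nodes, el, fx$targets)
      expect_equal(got$s_net, want$s_net, tolerance = 1e-12)
      expect_equal(got$n_targets, want$n_targets)
    }
  }
})

test_that("ranking is sorted, tie-broken by term, and scale invariant", {
  fx <- gen_network_fixture(80, 200, 5, 15, 12, seed = 2)
  subnets <- extract_subnetworks(fx$graph, fx$term2nodes)
  tab <- rank_perturbed(subnets, fx$targets, fx$graph)
  expect_true(all(diff(tab$s_net) <= 1e-12))
  tab_scaled <- rank_perturbed(subnets, fx$targets * 0.37, fx$graph)
  expect_equal(tab$term, tab_scaled$term)
  expect_equal(tab_scaled$s_net, 0.37 * tab$s_net, tolerance = 1e-12)
  one <- rank_perturbed(subnets[1], fx$targets, fx$graph)
  expect_equal(nrow(one), 1L)
})

test_that("target-differential interaction pairs come only from edges", {
  g <- mk_graph(rbind(c("T1", "D1"), c("T1", "D2"), c("D1", "D2"), c("U", "V")))
  pairs <- interaction_overlap("T1", c("D1", "D2"), g)
  expect_equal(pairs, data.frame(target = c("T1", "T1"),
                                 de_protein = c("D1", "D2"),
                                 stringsAsFactors = FALSE))
  # disjoint graph
  expect_equal(nrow(interaction_overlap("A", "B", g)), 0L)
  # shared membership alone creates no pair
  g2 <- mk_graph(rbind(c("X", "Y")))
  expect_equal(nrow(interaction_overlap("X", "X", g2)), 0L)
})
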
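test_that("pull-down fixtures respect cardinalities and are seed-deterministic", {
  fx <- gen_pulldown_fixture(265, 104, 106, seed = 1)
  expect_length(fx$identified, 265)
  expect_length(fx$sticky, 104)
  expect_length(fx$central, 106)
  expect_true(all(fx$sticky %in% fx$identified))
  expect_true(all(fx$central %in% setdiff(fx$identified, fx$sticky)))
  expect_true(all(names(fx$crapome_counts) %in% fx$identified))
  expect_true(all(fx$crapome_counts >= 0))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", fx$sequences)))
  expect_identical(fx, gen_pulldown_fixture(265, 104, 106, seed = 1))
  expect_error(gen_pulldown_fixture(10, 8, 5, seed = 1), "must not exceed")
  # no flags: deconvolution is the identity
  fx0 <- gen_pulldown_fixture(10, 0, 0, seed = 7)
  expect_equal(deconvolve(fx0)$report$n_filtered, 10L)
})

test_that("reporter spectra are exact mixtures, clipped non-negative", {
  tpl <- reporter_templates()
  pure <- gen_reporter_spectrum(c(1, 0, 0, 0), tpl)
  expect_equal(pure$intensity, tpl[[1]]$intensity)
  mix <- gen_reporter_spectrum(c(1, 2, 1, 0.5), tpl)
  manual <- tpl[[1]]$intensity + 2 * tpl[[2]]$intensity +
    tpl[[3]]$intensity + 0.5 * tpl[[4]]$intensity
  expect_equal(mix$intensity, manual)
  noisy <- gen_reporter_spectrum(c(1, 2, 1, 0.5), tpl, noise_frac = 0.5, seed = 5)
  expect_true(all(noisy$intensity >= 0))
  expect_identical(noisy, gen_reporter_spectrum(c(1, 2, 1, 0.5), tpl,
                                                noise_frac = 0.5, seed = 5))
  expect_error(gen_reporter_spectrum(c(-1, 0, 0, 0), tpl), "non-negative")
})

test_that("iTRAQ experiments carry coherent ground truth", {
  ex <- gen_itraq_experiment(50, 0.2, 4, 2, 0.2, 0.04, 0.04, seed = 11)
  expect_length(ex$spectra, 100)
  expect_true(all(ex$peptide_map %in% ex$proteins))
  expect_equal(unname(table(ex$peptide_map)[ex$proteins[1]]), 2)
  expect_true(all(ex$true_ratio > 0))
  reg <- ex$regulated
  expect_length(reg, 10)
  expect_true(all(apply(ex$true_ratio[reg, , drop = FALSE], 1,
                        function(r) any(r != 1))))
  unreg <- setdiff(ex$proteins, c(reg, ex$on_proteins, ex$off_proteins))
  expect_true(all(ex$true_ratio[unreg, ] == 1))
  expect_true(all(ex$onoff_truth[ex$on_proteins, ] == "ON"))
  expect_equal(sum(ex$onoff_truth[ex$off_proteins, ] == "OFF"),
               length(ex$off_proteins))
  expect_identical(ex, gen_itraq_experiment(50, 0.2, 4, 2, 0.2, 0.04, 0.04,
                                            seed = 11))
  expect_error(gen_itraq_experiment(10, 0.5, 0, 1, 0, 0, 0, seed = 1), "positive")
  expect_error(gen_itraq_experiment(10, 0.6, 2, 1, 0, 0.3, 0.3, seed = 1),
               "sum to at most 1")
})

test_that("the null experiment has unit ratios and exact spectra", {
  ex <- gen_itraq_experiment(5, 0, 1.5, 1, 0, 0, 0, seed = 2)
  expect_true(all(ex$true_ratio == 1))
  f <- fit_reporter_ratios(ex$spectra[[1]], ex$templates)
  expect_equal(f$ratios, c(1, 1, 1, 1), tolerance = 1e-9)
})

test_that("network fixtures are connected simple graphs with connected terms", {
  fx <- gen_network_fixture(40, 80, 2, 10, 5, seed = 1)
  g <- fx$graph
  expect_equal(igraph::vcount(g), 40)
  expect_equal(igraph::ecount(g), 80)
  expect_true(igraph::is_connected(g))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  for (term in names(fx$term2nodes)) {
    sub <- igraph::induced_subgraph(g, fx$term2nodes[[term]])
    expect_true(igraph::is_connected(sub))
    expect_length(fx$term2nodes[[term]], 10)
  }
  expect_length(fx$targets, 5)
  expect_equal(max(fx$targets), 1)
  expect_true(all(fx$targets > 0))
  fx2 <- gen_network_fixture(40, 80, 2, 10, 5, seed = 1)
  expect_identical(igraph::as_edgelist(fx$graph), igraph::as_edgelist(fx2$graph))
  expect_identical(fx$term2nodes, fx2$term2nodes)
  expect_identical(fx$targets, fx2$targets)
  expect_identical(fx$placement, fx2$placement)
  expect_error(gen_network_fixture(40, 10, 1, 5, 2, seed = 1), "connected")
  expect_error(gen_network_fixture(10, 20, 1, 15, 2, seed = 1), "term_size")
  # no targets: every subnetwork scores 0
  fx0 <- gen_network_fixture(40, 80, 1, 10, 0, seed = 1)
  sn <- extract_subnetworks(fx0$graph, fx0$term2nodes)
  expect_equal(s_net(sn[[1]], fx0$targets, fx0$graph)$s_net, 0)
})

test_that("reference tables load with the published shapes and entries", {
  tabs <- cigb552_tables()
  expect_equal(nrow(tabs$targets), 55L)
  expect_equal(nrow(tabs$subnetworks), 10L)
  expect_equal(nrow(tabs$differential), 72L)
  t1 <- tabs$targets
  expect_equal(t1$empai[t1$gene == "C1QBP"], 1.74)
  expect_equal(t1$score[t1$gene == "C1QBP"], 648)
  t2 <- tabs$subnetworks
  row <- t2[t2$go_id == "GO:0045786", ]
  expect_equal(row$nodes, 37)
  expect_equal(row$targets, 8)
  expect_equal(row$s_net, 0.076)
  t3 <- tabs$differential
  mcm6 <- t3[t3$gene == "MCM6", ]
  expect_equal(unlist(mcm6[, paste0("fc_", TIMEPOINTS)], use.names = FALSE),
               c(-4.2, -1.1, -2))
  expect_equal(attr(t3, "thresholds"), c(`40min` = 2.6, `2h` = 2.6, `5h` = 2.4))
  expect_equal(sum(t3$chem_overlap), 8L)
})
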